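test_that("canonical core scanning finds the documented motifs", {
  # STBD1-like context: WEMV core at position 203
  stbd1 <- carrier_protein("DWEMVNI", at = 202L)
  expect_true(203L %in% scan_clir_cores(stbd1))
  expect_equal(substr(stbd1, 203, 206), "WEMV")

  # ATG4B-like context: YDTL core at position 8
  atg4b <- carrier_protein("YDTLCNI", at = 8L, total = 40L)
  expect_true(8L %in% scan_clir_cores(atg4b))

  expect_equal(scan_clir_cores("CEMV"), integer(0))
  expect_equal(scan_clir_cores("FAALWAAV"), c(1L, 5L))
  expect_equal(scan_clir_cores("FAA"), integer(0))
})

test_that("core scanning agrees with a position-by-position oracle", {
  set.seed(101)
  aa <- setdiff(lir_alphabet(), "*")
  for (i in seq_len(10000)) {
    sq <- paste(sample(aa, sample(4:30, 1), replace = TRUE), collapse = "")
    expect_identical(scan_clir_cores(sq), naive_scan(sq))
  }
})

test_that("window extraction pads termini and always returns 18 characters", {
  long <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 2), collapse = "")

  # core at position 8: exact fit, window = residues 1-18
  expect_equal(extract_window(long, 8L), substr(long, 1, 18))

  # core at position 2: six leading pads
  w <- extract_window(long, 2L)
  expect_equal(substr(w, 1, 6), "******")
  expect_equal(substr(w, 7, 18), substr(long, 1, 12))

  # 4-residue protein: pads on both sides
  expect_equal(extract_window("WEMV", 1L), paste0(strrep("*", 7), "WEMV",
                                                  strrep("*", 7)))

  expect_error(extract_window("WEMV", 2L), "does not fit")
  expect_error(extract_window("WEMV", 0L), "does not fit")

  set.seed(7)
  for (i in 1:50) {
    n <- sample(4:60, 1)
    sq <- paste(sample(setdiff(lir_alphabet(), "*"), n, TRUE), collapse = "")
    s <- sample(seq_len(n - 3L), 1)
    expect_equal(nchar(extract_window(sq, s)), 18L)
  }
})

test_that("benchmark assembly separates annotated positives from regex negatives", {
  # one protein, two regex cores, one annotated -> 1 positive + 1 negative
  prot <- tibble::tibble(
    accession = "P1",
    sequence = carrier_protein("WEMVAAAAAAAAYAAL", at = 30L, total = 80L)
  )
  expect_equal(length(scan_clir_cores(prot$sequence)), 2L)
  bm <- build_benchmark(prot, tibble::tibble(accession = "P1", core_start = 30L))
  expect_equal(sum(bm$label == "positive"), 1L)
  expect_equal(sum(bm$label == "negative"), 1L)
  expect_equal(bm$core_start[bm$label == "negative"], 42L)

  # an annotated atypical motif (core not matching the regex) stays positive
  prot2 <- tibble::tibble(accession = "P2",
                          sequence = carrier_protein("AEMI", at = 30L, total = 80L))
  bm2 <- build_benchmark(prot2, tibble::tibble(accession = "P2", core_start = 30L))
  expect_equal(bm2$motif_class[bm2$label == "positive"], "aLIR")
  expect_false(30L %in% bm2$core_start[bm2$label == "negative"])

  # a regex core overlapping the positive span is excluded from negatives:
  # WEFVIL holds cores at 30 (WEFV) and 32 (FVIL), spans overlapping
  prot3 <- tibble::tibble(accession = "P3",
                          sequence = carrier_protein("WEFVIL", at = 30L,
                                                     total = 80L))
  expect_setequal(scan_clir_cores(prot3$sequence), c(30L, 32L))
  bm3 <- build_benchmark(prot3, tibble::tibble(accession = "P3", core_start = 30L))
  expect_false(32L %in% bm3$core_start[bm3$label == "negative"])
  expect_equal(sum(bm3$label == "positive"), 1L)

  # annotation disagreeing with the sequence is an error
  expect_error(
    build_benchmark(prot, tibble::tibble(accession = "P1", core_start = 30L,
                                         core_seq = "YDTL")),
    "expects core"
  )
  expect_error(
    build_benchmark(prot, tibble::tibble(accession = "ZZ", core_start = 3L)),
    "absent"
  )
})

test_that("benchmark negatives + regex positives tile the core scan without overlaps", {
  set.seed(31)
  sim <- small_sim(seed = 31L)
  bm <- sim$benchmark
  for (acc in unique(bm$accession)[1:10]) {
    sq <- sim$proteins$sequence[sim$proteins$accession == acc]
    cores <- scan_clir_cores(sq)
    sub <- bm[bm$accession == acc, ]
    pos_cores <- sub$core_start[sub$label == "positive"]
    neg_cores <- sub$core_start[sub$label == "negative"]
    # negatives and regex-matching positives are disjoint and all come from
    # the scan
    expect_length(intersect(pos_cores, neg_cores), 0L)
    expect_true(all(neg_cores %in% cores))
    # inverting the overlap exclusion recovers the full scan
    excluded <- cores[vapply(cores, function(s) {
      any(s + 3L >= pos_cores & s <= pos_cores + 3L)
    }, logical(1))]
    expect_setequal(c(neg_cores, excluded), cores)
  }
})

test_that("duplicate annotations collapse to one positive", {
  prot <- tibble::tibble(accession = "P1",
                         sequence = carrier_protein("WEMV", at = 30L, total = 80L))
  ann <- tibble::tibble(accession = c("P1", "P1"), core_start = c(30L, 30L))
  bm <- build_benchmark(prot, ann)
  expect_equal(sum(bm$label == "positive"), 1L)
})
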