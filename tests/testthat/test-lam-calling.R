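test_that("variants apply cleanly and reference mismatches are caught", {
  stbd1 <- carrier_protein("DWEMVNI", at = 202L)
  v <- list(position = 203L, ref_aa = "W", alt_aa = "C")
  mut <- apply_variant(list(accession = "STBD1", sequence = stbd1), v)
  expect_equal(substr(mut, 203, 206), "CEMV")
  expect_equal(nchar(mut), nchar(stbd1))
  expect_length(intersect(203L, scan_clir_cores(mut)), 0L)

  atg4b <- carrier_protein("YDTLCNI", at = 8L, total = 60L)
  mut2 <- apply_variant(list(accession = "ATG4B", sequence = atg4b),
                        list(position = 8L, ref_aa = "Y", alt_aa = "C"))
  expect_false(8L %in% scan_clir_cores(mut2))

  expect_error(
    apply_variant(list(accession = "STBD1", sequence = stbd1),
                  list(position = 203L, ref_aa = "A", alt_aa = "C")),
    "mismatch"
  )
  expect_error(
    apply_variant(list(accession = "STBD1", sequence = stbd1),
                  list(position = 10000L, ref_aa = "W", alt_aa = "C")),
    "outside"
  )
})

test_that("candidate enumeration tags core origin and respects window bounds", {
  # anchor-destroying variant: core exists only in the original
  sq <- carrier_protein("WEMV", at = 50L, total = 120L)
  mut <- apply_variant(list(accession = "P", sequence = sq),
                       list(position = 50L, ref_aa = "W", alt_aa = "C"))
  cand <- enumerate_lam_candidates(sq, mut, 50L)
  expect_equal(cand$core_origin[cand$core_start == 50L], "original")

  # anchor-creating variant: core exists only in the mutant
  sq2 <- carrier_protein("PEMV", at = 50L, total = 120L)
  mut2 <- apply_variant(list(accession = "P", sequence = sq2),
                        list(position = 50L, ref_aa = "P", alt_aa = "W"))
  cand2 <- enumerate_lam_candidates(sq2, mut2, 50L)
  expect_equal(cand2$core_origin[cand2$core_start == 50L], "mutant")

  # a core untouched by the substitution appears on both sides
  sq3 <- carrier_protein("WEMVAAAAAAQ", at = 50L, total = 120L)
  mut3 <- apply_variant(list(accession = "P", sequence = sq3),
                        list(position = 60L, ref_aa = "Q", alt_aa = "N"))
  cand3 <- enumerate_lam_candidates(sq3, mut3, 60L)
  expect_equal(cand3$core_origin[cand3$core_start == 50L], "both")

  # windows only reach 7 upstream / 10 downstream of the core start
  cand_far <- enumerate_lam_candidates(sq, mut, 50L + 18L)
  expect_false(50L %in% cand_far$core_start)
  expect_true(all(enumerate_lam_candidates(sq, sq, 55L)$core_start >= 45L))
  expect_true(all(enumerate_lam_candidates(sq, sq, 55L)$core_start <= 62L))
})

test_that("calls carry the verdict semantics of the score and p thresholds", {
  sim <- small_sim(seed = 103L)
  model <- lir_model(dplyr::filter(sim$benchmark, label == "positive"))
  cfg <- lir_config(seed = 3L)
  cal <- calibrate_model(model, sim$benchmark, cfg)
  vars <- generate_variants(sim, n_loss = 5L, n_gain = 3L, n_neutral = 150L,
                            seed = 103L)
  vars <- dplyr::distinct(vars, accession, position, ref_aa, alt_aa,
                          .keep_all = TRUE)
  calls <- call_lams(sim$proteins, vars, model, cal, config = cfg)

  expect_true(all(calls$x >= 0 & calls$x <= 1))
  expect_true(all(calls$y >= 0 & calls$y <= 1))
  t1 <- calls$verdict == "TypeI"
  expect_true(all(calls$y[t1] > calls$x[t1]))
  expect_true(all(calls$y[t1] > cfg$score_threshold))
  expect_true(all(calls$p_value[t1] < cfg$p_threshold))
  t2 <- calls$verdict == "TypeII"
  expect_true(all(calls$x[t2] > calls$y[t2]))
  expect_true(all(calls$x[t2] > cfg$score_threshold))
  expect_true(all(calls$p_value[t2] < cfg$p_threshold))

  # summary mode keeps the minimum-p row per variant
  summ <- call_lams(sim$proteins, vars, model, cal, config = cfg,
                    summarise = TRUE)
  expect_lte(nrow(summ), nrow(dplyr::distinct(vars, accession, position,
                                              ref_aa, alt_aa)))
  one <- dplyr::semi_join(calls, summ[1, c("accession", "position")],
                          by = c("accession", "position"))
  expect_equal(min(one$p_value), summ$p_value[1])

  # restriction filters by accession
  keep <- unique(calls$accession)[1]
  restr <- call_lams(sim$proteins, vars, model, cal, config = cfg,
                     restrict_to = keep)
  expect_true(all(restr$accession == keep))
})

test_that("swapping original and mutant exchanges gains with losses", {
  sim <- small_sim(seed = 107L)
  model <- lir_model(dplyr::filter(sim$benchmark, label == "positive"))
  cfg <- lir_config(seed = 3L)
  cal <- calibrate_model(model, sim$benchmark, cfg)
  vars <- generate_variants(sim, n_loss = 4L, n_gain = 2L, n_neutral = 120L,
                            seed = 107L)
  # one variant per protein so the jointly mutated proteome inverts exactly
  vars <- dplyr::distinct(vars, accession, .keep_all = TRUE)
  calls <- call_lams(sim$proteins, vars, model, cal, config = cfg)

  # apply every variant to get the mutant proteome, then call the reverse
  # variants against it with the same pair density
  seq_of <- stats::setNames(sim$proteins$sequence, sim$proteins$accession)
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, ]
    seq_of[[v$accession]] <- apply_variant(
      list(accession = v$accession, sequence = seq_of[[v$accession]]), v)
  }
  mut_prot <- tibble::tibble(accession = names(seq_of),
                             sequence = unname(seq_of))
  rev_vars <- dplyr::mutate(vars, tmp = ref_aa, ref_aa = alt_aa, alt_aa = tmp)
  dens <- fit_pair_density(cbind(calls$x, calls$y), cfg)
  fwd <- call_lams(sim$proteins, vars, model, cal, density = dens, config = cfg)
  rev <- call_lams(mut_prot, rev_vars, model, cal, density = dens, config = cfg)

  key <- function(d) paste(d$accession, d$position, d$core_start)
  common <- intersect(key(fwd), key(rev))
  f <- fwd[match(common, key(fwd)), ]
  r <- rev[match(common, key(rev)), ]
  expect_equal(f$x, r$y)
  expect_equal(f$y, r$x)
  # the deterministic part of the verdict (direction + score gate) flips
  # exactly; the conditional p-value conditions on the original score, so it
  # is not swap-symmetric under an asymmetric corpus density
  cand <- function(d) dplyr::case_when(
    d$y > d$x & d$y > cfg$score_threshold ~ "gain",
    d$x > d$y & d$x > cfg$score_threshold ~ "loss",
    TRUE ~ "none")
  swap <- c(gain = "loss", loss = "gain", none = "none")
  expect_equal(unname(swap[cand(f)]), cand(r))
})

test_that("a substitution invisible to the scorer yields a p = 1 tie", {
  # zero weight at window position 1 makes an offset -7 substitution silent
  sim <- small_sim(seed = 109L)
  ref <- dplyr::filter(sim$benchmark, label == "positive")
  w <- rep(1, 18); w[1] <- 0
  model <- lir_model(ref, weights = w)
  cfg <- lir_config(seed = 3L)
  cal <- calibrate_model(model, sim$benchmark, cfg)

  host <- ref[1, ]
  sq <- sim$proteins$sequence[sim$proteins$accession == host$accession]
  pos7 <- host$core_start - 7L
  ref_aa <- substr(sq, pos7, pos7)
  alt_aa <- setdiff(c("A", "G", "N", "Q"), c(ref_aa, "*"))[1]
  vars <- tibble::tibble(accession = host$accession, position = pos7,
                         ref_aa = ref_aa, alt_aa = alt_aa)
  dens <- lam_density(cbind(c(0.2, 0.8), c(0.2, 0.8)), h = 0.05)
  calls <- call_lams(sim$proteins, vars, model, cal, density = dens,
                     config = cfg)
  row <- calls[calls$core_start == host$core_start, ]
  expect_equal(row$x, row$y)
  expect_equal(row$p_value, 1)
  expect_equal(row$verdict, "none")
})

test_that("reference mismatches are skippable in batch mode", {
  sq <- carrier_protein("WEMV", at = 50L, total = 120L)
  prot <- tibble::tibble(accession = "P", sequence = sq)
  vars <- tibble::tibble(accession = "P", position = 50L,
                         ref_aa = "F", alt_aa = "C")
  cal <- lir_calibration(pos_points = c(.6, .8), neg_points = c(.2, .4),
                         h_pos = .05, h_neg = .05, prior_pos = .9,
                         scale_min = 0, scale_max = 100)
  model <- lir_model(tiny_reference("DDSSTTEWSSLVEEDDSS"))
  expect_error(call_lams(prot, vars, model, cal), "mismatch")
  expect_warning(
    out <- call_lams(prot, vars, model, cal, on_mismatch = "skip"),
    "mismatch"
  )
  expect_equal(nrow(out), 0L)
})
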