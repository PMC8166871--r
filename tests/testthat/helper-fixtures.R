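# Shared fixtures and independent oracles. Everything is generated in code;
# no files are shipped.

# a carrier protein embedding a given core context at a given position,
# padded with alanines
carrier_protein <- function(context, at, total = at + nchar(context) + 20L) {
  pre <- strrep("A", at - 1L)
  post <- strrep("A", total - (at - 1L) - nchar(context))
  paste0(pre, context, post)
}

random_window <- function(alphabet = lirmotif::lir_alphabet()) {
  paste(sample(alphabet, 18L, replace = TRUE), collapse = "")
}

tiny_reference <- function(windows, accessions = NULL) {
  tibble::tibble(
    accession = accessions %||% paste0("R", seq_along(windows)),
    core_start = 8L,
    window_seq = windows
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# naive double-loop implementation of the average weighted similarity score
naive_similarity <- function(query, refs, M, W) {
  q <- strsplit(query, "")[[1]]
  total <- 0
  for (j in seq_len(18L)) {
    s <- 0
    for (r in refs) s <- s + M[q[j], strsplit(r, "")[[1]][j]]
    total <- total + s * W[j]
  }
  total / length(refs)
}

# position-by-position regex oracle for canonical core scanning
naive_scan <- function(sequence) {
  n <- nchar(sequence)
  hits <- integer(0)
  if (n < 4L) return(hits)
  for (s in seq_len(n - 3L)) {
    if (substr(sequence, s, s) %in% c("F", "W", "Y") &&
        substr(sequence, s + 3L, s + 3L) %in% c("L", "I", "V")) {
      hits <- c(hits, s)
    }
  }
  hits
}

# brute-force AUC by enumeration of all positive x negative pairs
naive_auc <- function(score, label) {
  pos <- score[label == "positive"]
  neg <- score[label == "negative"]
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos) * length(neg))
}

# exhaustive hypergeometric upper tail by enumerating draw compositions
naive_hyper_tail <- function(N, n, M, m) {
  total <- choose(N, n)
  sum(vapply(m:min(n, M), function(mp) {
    choose(M, mp) * choose(N - M, n - mp)
  }, numeric(1))) / total
}

# a small planted-signal simulation reused by several test files
small_sim <- function(seed = 1L, n_pos = 40L, n_proteins = 25L,
                      protein_length = 240L, signal_strength = 1) {
  generate_benchmark(n_pos = n_pos, n_proteins = n_proteins,
                     protein_length = protein_length,
                     signal_strength = signal_strength,
                     n_nearmiss = 8L, seed = seed)
}
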