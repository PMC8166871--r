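# Calling LIR-motif-associated mutations (LAMs): enumerate the candidate
# cores whose 18-residue window covers a missense variant, score the original
# and mutant windows, calibrate both to posteriors (x, y), and test the
# mutant score against the conditional Parzen density. Type I calls gain
# predicted LC3 binding (y > x, y > 0.5), Type II lose it (x > y, x > 0.5);
# both require the conditional tail p-value below the threshold.

#' Apply a missense variant to a protein sequence
#'
#' @param protein One-row tibble (or list) with `accession` and `sequence`.
#' @param variant One-row tibble (or list) with `position`, `ref_aa`,
#'   `alt_aa`.
#' @return The mutant sequence string.
#' @export
apply_variant <- function(protein, variant) {
  sq <- protein$sequence
  pos <- variant$position
  if (pos < 1L || pos > nchar(sq)) {
    stop("variant position ", pos, " outside ", protein$accession,
         " (length ", nchar(sq), ")")
  }
  found <- substr(sq, pos, pos)
  if (found != variant$ref_aa) {
    stop("reference mismatch at ", protein$accession, ":", pos,
         " expected ", variant$ref_aa, ", sequence has ", found)
  }
  paste0(substr(sq, 1L, pos - 1L), variant$alt_aa,
         substr(sq, pos + 1L, nchar(sq)))
}

#' Enumerate candidate cores affected by a variant
#'
#' A core start s is a candidate when its 18-residue window
#' \[s - 7, s + 10\] covers the variant position (so s ranges over
#' \[pos - 10, pos + 7\]) and the tetrapeptide at s matches the canonical
#' regex in the original sequence, the mutant sequence, or both. The origin
#' tag records which side carries the core, so anchor-destroying
#' (`"original"`) and anchor-creating (`"mutant"`) mutations are both
#' representable.
#'
#' @param sequence Original protein sequence.
#' @param mutant_sequence Sequence after [apply_variant()].
#' @param position Variant position (1-based).
#' @return Tibble with columns `core_start` and `core_origin`
#'   (`"original"`, `"mutant"`, or `"both"`).
#' @export
enumerate_lam_candidates <- function(sequence, mutant_sequence, position) {
  n <- nchar(sequence)
  lo <- max(1L, position - 10L)
  hi <- min(n - CORE_LEN + 1L, position + 7L)
  if (hi < lo) {
    return(tibble::tibble(core_start = integer(), core_origin = character()))
  }
  in_range <- function(s) s[s >= lo & s <= hi]
  orig <- in_range(scan_clir_cores(sequence))
  mut <- in_range(scan_clir_cores(mutant_sequence))
  all_s <- sort(union(orig, mut))
  if (length(all_s) == 0L) {
    return(tibble::tibble(core_start = integer(), core_origin = character()))
  }
  tibble::tibble(
    core_start = all_s,
    core_origin = dplyr::case_when(
      all_s %in% orig & all_s %in% mut ~ "both",
      all_s %in% orig ~ "original",
      TRUE ~ "mutant"
    )
  )
}

#' Call Type I / Type II LIR-motif-associated mutations
#'
#' For every variant, enumerates candidate cores, scores the original and
#' mutant windows with the model, calibrates both to posteriors `x` and `y`,
#' and computes the conditional tail p-value of `y` given `x` under the pair
#' density: mutations with `y > x` are tested as gains, `y < x` as losses,
#' `y == x` is never significant (p = 1). Verdicts: `TypeI` when `y > x`,
#' `y > score_threshold` and `p < p_threshold`; `TypeII` when `x > y`,
#' `x > score_threshold` and `p < p_threshold`; otherwise `none`.
#'
#' @param proteins Tibble with `accession`, `sequence`.
#' @param variants Tibble of missense variants (`accession`, `position`,
#'   `ref_aa`, `alt_aa`).
#' @param model A [lir_model()].
#' @param calibration A [lir_calibration()].
#' @param density Optional prefitted [lam_density()]; when `NULL`, the
#'   density is fitted to this call set's own (x, y) pairs, mirroring the
#'   corpus-wide fit of the full pipeline.
#' @param config A [lir_config()] (p and score thresholds, bandwidth grid).
#' @param on_mismatch `"error"` to stop on a reference-residue mismatch,
#'   `"skip"` to drop the variant with a warning.
#' @param restrict_to Optional accession vector; calls are kept only for
#'   these proteins (e.g. a curated autophagy-protein list).
#' @param summarise Keep only the minimum-p row per variant.
#' @return Tibble with one row per (variant, candidate core): variant fields,
#'   `core_start`, `core_origin`, raw scores `score_x`/`score_y`, posteriors
#'   `x`/`y`, `p_value`, `verdict`.
#' @export
call_lams <- function(proteins, variants, model, calibration, density = NULL,
                      config = lir_config(), on_mismatch = c("error", "skip"),
                      restrict_to = NULL, summarise = FALSE) {
  on_mismatch <- match.arg(on_mismatch)
  stopifnot(inherits(model, "lir_model"),
            inherits(calibration, "lir_calibration"))
  seq_of <- stats::setNames(proteins$sequence, proteins$accession)

  rows <- purrr::map_dfr(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    if (!v$accession %in% names(seq_of)) {
      warning("variant ", i, ": accession ", v$accession,
              " absent from proteins; skipped")
      return(NULL)
    }
    sq <- seq_of[[v$accession]]
    mut <- tryCatch(
      apply_variant(list(accession = v$accession, sequence = sq), v),
      error = function(e) {
        if (on_mismatch == "error") stop(e)
        warning(conditionMessage(e), "; variant skipped")
        NULL
      })
    if (is.null(mut)) return(NULL)
    cand <- enumerate_lam_candidates(sq, mut, v$position)
    if (nrow(cand) == 0L) return(NULL)
    tibble::tibble(
      accession = v$accession, position = v$position,
      ref_aa = v$ref_aa, alt_aa = v$alt_aa,
      core_start = cand$core_start, core_origin = cand$core_origin,
      window_orig = extract_windows(sq, cand$core_start),
      window_mut = extract_windows(mut, cand$core_start)
    )
  })
  if (nrow(rows) == 0L) {
    return(tibble::tibble(accession = character(), position = integer(),
                          ref_aa = character(), alt_aa = character(),
                          core_start = integer(), core_origin = character(),
                          score_x = numeric(), score_y = numeric(),
                          x = numeric(), y = numeric(),
                          p_value = numeric(), verdict = character()))
  }

  rows$score_x <- score_windows(tibble::tibble(window_seq = rows$window_orig),
                                model)$score
  rows$score_y <- score_windows(tibble::tibble(window_seq = rows$window_mut),
                                model)$score
  rows$x <- bpp_transform(rows$score_x, calibration)
  rows$y <- bpp_transform(rows$score_y, calibration)
  rows$window_orig <- NULL
  rows$window_mut <- NULL

  if (is.null(density)) {
    density <- fit_pair_density(cbind(rows$x, rows$y), config)
  }
  direction <- ifelse(rows$y > rows$x, "gain", "loss")
  rows$p_value <- rep(1, nrow(rows))
  moved <- rows$y != rows$x
  if (any(moved)) {
    rows$p_value[moved] <- conditional_pvalues(
      density, rows$x[moved], rows$y[moved], direction[moved])
  }
  rows$verdict <- dplyr::case_when(
    is.na(rows$p_value) ~ "none",
    rows$y > rows$x & rows$y > config$score_threshold &
      rows$p_value < config$p_threshold ~ "TypeI",
    rows$x > rows$y & rows$x > config$score_threshold &
      rows$p_value < config$p_threshold ~ "TypeII",
    TRUE ~ "none"
  )

  if (!is.null(restrict_to)) {
    rows <- dplyr::filter(rows, .data$accession %in% restrict_to)
  }
  if (summarise) {
    rows <- rows |>
      dplyr::group_by(.data$accession, .data$position, .data$ref_aa,
                      .data$alt_aa) |>
      dplyr::slice_min(.data$p_value, n = 1L, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  rows
}
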