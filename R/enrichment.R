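# Hypergeometric over-representation of annotation terms in a query protein
# set. With N = proteins annotated by at least one term, n = proteins under a
# term, M = query proteins inside the universe, and m = query proteins under
# the term:
#
#   E-ratio = (m / M) / (n / N)
#   p = sum_{m' = m}^{n} C(M, m') C(N - M, n - m') / C(N, n),  for E-ratio > 1

#' Hypergeometric term enrichment
#'
#' @param annotations Tibble with columns `term` and `accession` (one row per
#'   term membership). The universe is every accession annotated by at least
#'   one term.
#' @param query Character vector of query accessions; intersected with the
#'   universe before testing.
#' @param adjust Apply Benjamini-Hochberg correction (`p_adjusted` column).
#' @return Tibble sorted by p-value with columns `term`, `n_term` (n),
#'   `m_overlap` (m), `e_ratio`, `p_value` (NA unless `e_ratio > 1`), and
#'   `p_adjusted` when `adjust = TRUE`.
#' @export
enrich_terms <- function(annotations, query, adjust = FALSE) {
  stopifnot(all(c("term", "accession") %in% names(annotations)))
  ann <- dplyr::distinct(tibble::as_tibble(annotations),
                         .data$term, .data$accession)
  universe <- unique(ann$accession)
  N <- length(universe)
  q <- intersect(unique(query), universe)
  M <- length(q)
  if (M == 0L) stop("query set is disjoint from the annotated universe")

  res <- ann |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(n_term = dplyr::n(),
                     m_overlap = sum(.data$accession %in% q),
                     .groups = "drop") |>
    dplyr::mutate(
      e_ratio = (.data$m_overlap / M) / (.data$n_term / N),
      p_value = dplyr::if_else(
        .data$e_ratio > 1,
        stats::phyper(.data$m_overlap - 1, M, N - M, .data$n_term,
                      lower.tail = FALSE),
        NA_real_)
    ) |>
    dplyr::arrange(.data$p_value)
  if (adjust) {
    res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  }
  res
}
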