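# Canonical-LIR core detection and 18-residue motif window extraction.
#
# A motif window spans positions core_start-7 .. core_start+10 of the protein
# (the 4-residue core plus 7 flanking residues each side, 18 characters in
# all); positions falling outside the sequence are padded with '*'. Within
# the window the core occupies offsets 8-11 (1-based).

WINDOW_LEN <- 18L
FLANK <- 7L
CORE_LEN <- 4L
CLIR_REGEX <- "[FWY]..[LIV]"

#' Find canonical LIR cores in a protein sequence
#'
#' Returns every 1-based start position of a tetrapeptide matching the
#' canonical LIR pattern `[FWY]XX[LIV]` (aromatic anchor, any two residues,
#' aliphatic anchor). Overlapping matches are all reported.
#'
#' @param sequence An amino-acid string (a single protein sequence).
#' @return Integer vector of core start positions (possibly empty).
#' @export
scan_clir_cores <- function(sequence) {
  n <- nchar(sequence)
  if (n < CORE_LEN) return(integer(0))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  starts <- which(chars %in% c("F", "W", "Y"))
  starts <- starts[starts + 3L <= n]
  starts[chars[starts + 3L] %in% c("L", "I", "V")]
}

#' Extract one 18-residue motif window
#'
#' @param sequence Protein sequence string.
#' @param core_start 1-based start of the tetrapeptide core; the core must
#'   lie fully inside the sequence.
#' @return An 18-character window string, `*`-padded where the flanks run
#'   past the protein termini.
#' @export
extract_window <- function(sequence, core_start) {
  n <- nchar(sequence)
  if (core_start < 1L || core_start + CORE_LEN - 1L > n) {
    stop("core at ", core_start, " does not fit in a sequence of length ", n)
  }
  lo <- core_start - FLANK
  hi <- core_start + CORE_LEN - 1L + FLANK
  body <- substr(sequence, max(lo, 1L), min(hi, n))
  paste0(strrep("*", max(0L, 1L - lo)), body, strrep("*", max(0L, hi - n)))
}

#' Extract several windows from one protein
#'
#' Vectorized companion of [extract_window()].
#'
#' @param sequence Protein sequence string.
#' @param core_starts Integer vector of 1-based core starts.
#' @return Character vector of 18-residue windows.
#' @export
extract_windows <- function(sequence, core_starts) {
  vapply(core_starts, function(s) extract_window(sequence, s), character(1))
}

#' Build a positive/negative motif benchmark
#'
#' Positives are the annotated motif windows (canonical and atypical alike);
#' negatives are every canonical-regex core in the same proteins whose
#' 4-residue span does not overlap any annotated positive core span.
#' Duplicate (accession, core_start) entries within a label are collapsed.
#'
#' @param proteins Tibble with columns `accession`, `sequence`.
#' @param annotations Tibble of known motifs with columns `accession`,
#'   `core_start`, and optionally `core_seq` (verified against the sequence
#'   when present) and `motif_class` (`"cLIR"` or `"aLIR"`; inferred from the
#'   regex when absent). Extra columns are ignored.
#' @return A tibble with columns `accession`, `core_start`, `core_seq`,
#'   `motif_class`, `window_seq`, `label`.
#' @export
build_benchmark <- function(proteins, annotations) {
  stopifnot(all(c("accession", "sequence") %in% names(proteins)),
            all(c("accession", "core_start") %in% names(annotations)))
  missing <- setdiff(annotations$accession, proteins$accession)
  if (length(missing) > 0) {
    stop("annotated accession(s) absent from proteins: ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  seq_of <- stats::setNames(proteins$sequence, proteins$accession)

  ann <- dplyr::distinct(tibble::as_tibble(annotations),
                         .data$accession, .data$core_start, .keep_all = TRUE)
  ann$core_start <- as.integer(ann$core_start)

  pos <- purrr::pmap_dfr(
    list(ann$accession, ann$core_start, seq_len(nrow(ann))),
    function(acc, s, i) {
      sq <- seq_of[[acc]]
      if (s < 1L || s + CORE_LEN - 1L > nchar(sq)) {
        stop("annotation ", acc, ":", s, " outside sequence bounds")
      }
      core <- substr(sq, s, s + CORE_LEN - 1L)
      if ("core_seq" %in% names(ann) && !is.na(ann$core_seq[i]) &&
          !identical(core, ann$core_seq[i])) {
        stop("annotation ", acc, ":", s, " expects core '", ann$core_seq[i],
             "' but sequence has '", core, "'")
      }
      is_clir <- grepl(paste0("^", CLIR_REGEX, "$"), core)
      cls <- if ("motif_class" %in% names(ann) && !is.na(ann$motif_class[i])) {
        ann$motif_class[i]
      } else if (is_clir) "cLIR" else "aLIR"
      tibble::tibble(accession = acc, core_start = s, core_seq = core,
                     motif_class = cls, window_seq = extract_window(sq, s),
                     label = "positive")
    }
  )

  neg <- purrr::map_dfr(unique(ann$accession), function(acc) {
    sq <- seq_of[[acc]]
    cand <- scan_clir_cores(sq)
    pos_here <- pos$core_start[pos$accession == acc]
    # exclude any candidate whose 4-aa span overlaps a positive core span
    keep <- vapply(cand, function(s) {
      all(s + CORE_LEN - 1L < pos_here | s > pos_here + CORE_LEN - 1L)
    }, logical(1))
    cand <- cand[keep]
    if (length(cand) == 0L) return(NULL)
    tibble::tibble(
      accession = acc, core_start = cand,
      core_seq = vapply(cand, function(s) substr(sq, s, s + 3L), character(1)),
      motif_class = "cLIR",
      window_seq = extract_windows(sq, cand),
      label = "negative"
    )
  })

  dplyr::bind_rows(pos, neg)
}
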