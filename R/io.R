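#' Read protein sequences from a FASTA file
#'
#' Parses a protein FASTA file into a tibble of records. The accession is the
#' header token before the first whitespace; sequences are uppercased and
#' validated against the 24-letter alphabet (minus `*`, which is reserved for
#' window padding).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `accession` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  # tolerate stray blanks inside sequence lines, then parse with Biostrings
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, ">")
  lines[body] <- gsub("[ \t\r]", "", lines[body])
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  aas <- Biostrings::readAAStringSet(tmp)
  if (length(aas) == 0L) {
    return(tibble::tibble(accession = character(), sequence = character()))
  }
  acc <- sub("\\s.*$", "", names(aas))
  seqs <- toupper(as.character(aas))
  purrr::walk2(seqs, acc, validate_sequence)
  tibble::tibble(accession = unname(acc), sequence = unname(seqs))
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins Tibble with columns `accession` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  lines <- as.vector(rbind(paste0(">", proteins$accession), proteins$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein-level missense variant table
#'
#' Reads a TSV with columns `accession`, `position` (1-based residue index),
#' `ref_aa`, `alt_aa` and optionally `sample_id`. Rows duplicated on
#' (accession, position, ref_aa, alt_aa) are collapsed to one variant
#' (redundancy clearance); silent rows with `ref_aa == alt_aa` are dropped
#' with a warning.
#'
#' @param path Path to a tab-separated file with a header line.
#' @return A tibble of unique missense variants.
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("accession", "position", "ref_aa", "alt_aa")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("variant table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!is.numeric(tab$position) || any(tab$position != floor(tab$position))) {
    stop("variant positions must be integers (1-based residue index)")
  }
  tab <- dplyr::mutate(
    tab,
    position = as.integer(.data$position),
    ref_aa = toupper(.data$ref_aa),
    alt_aa = toupper(.data$alt_aa)
  )
  bad_aa <- !(tab$ref_aa %in% aa_canonical()) | !(tab$alt_aa %in% aa_canonical())
  if (any(bad_aa)) {
    stop("non-canonical ref/alt amino acid in row ", which(bad_aa)[1])
  }
  silent <- tab$ref_aa == tab$alt_aa
  if (any(silent)) {
    warning(sum(silent), " silent row(s) with ref_aa == alt_aa dropped")
    tab <- tab[!silent, , drop = FALSE]
  }
  dplyr::distinct(tab, .data$accession, .data$position, .data$ref_aa,
                  .data$alt_aa, .keep_all = TRUE)
}

#' Run configuration
#'
#' Bundles the tunable knobs shared across the pipeline stages. Every
#' stochastic stage (training proposals, fold assignment, bandwidth
#' subsampling, synthetic generation) draws from `seed` so a run is
#' reproducible end to end.
#'
#' @param seed Integer seed controlling all stochastic stages.
#' @param h_grid_step Bandwidth grid increment for maximum-likelihood
#'   selection; the grid spans (0, 1].
#' @param p_threshold Significance threshold on the conditional tail p-value
#'   of a call.
#' @param score_threshold Posterior-probability gate: Type I calls need
#'   mutant `y >` this, Type II calls original `x >` this.
#' @param stop_patience Consecutive rejected proposals that end a training
#'   phase.
#' @param kde_subsample When more score pairs than this are available,
#'   bandwidth likelihood is evaluated on a seeded uniform subsample.
#' @return A list of class `lir_config`.
#' @export
lir_config <- function(seed = 1L,
                       h_grid_step = 1e-4,
                       p_threshold = 0.01,
                       score_threshold = 0.5,
                       stop_patience = 1000L,
                       kde_subsample = 20000L) {
  stopifnot(h_grid_step > 0, h_grid_step < 1,
            p_threshold > 0, p_threshold < 1,
            score_threshold >= 0, score_threshold <= 1,
            stop_patience >= 1, kde_subsample >= 2)
  structure(
    list(seed = as.integer(seed),
         h_grid_step = h_grid_step,
         p_threshold = p_threshold,
         score_threshold = score_threshold,
         stop_patience = as.integer(stop_patience),
         kde_subsample = as.integer(kde_subsample)),
    class = "lir_config"
  )
}
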