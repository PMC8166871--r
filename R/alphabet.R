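# The 24-character scoring alphabet: 20 canonical amino acids plus the
# ambiguity codes B (D/N) and Z (E/Q), the unknown X, and '*', which this
# package uses to pad motif windows that run off a protein terminus.

#' The 24-letter scoring alphabet
#'
#' Twenty canonical amino acids plus `B`, `Z`, `X` and `*`. The order matches
#' the BLOSUM62 matrix returned by [blosum62()]; window padding introduces
#' `*`, which is scored through the matrix like any other character.
#'
#' @return Character vector of length 24.
#' @export
lir_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
    "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "X", "*")
}

# canonical residues only (valid ref/alt for missense variants)
aa_canonical <- function() lir_alphabet()[1:20]

.lirmotif_env <- new.env(parent = emptyenv())

#' BLOSUM62 over the 24-letter alphabet
#'
#' The published integer BLOSUM62 substitution matrix restricted to the
#' 24-character alphabet of [lir_alphabet()] (the NCBI distribution's extra
#' `J` ambiguity row/column is dropped). Values are returned as numeric so a
#' trained matrix, whose entries drift away from the integers, shares the
#' same representation.
#'
#' @return A symmetric 24 x 24 numeric matrix with dimnames.
#' @export
blosum62 <- function() {
  if (is.null(.lirmotif_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    ab <- lir_alphabet()
    m <- e$BLOSUM62[ab, ab]
    storage.mode(m) <- "double"
    .lirmotif_env$blosum62 <- m
  }
  .lirmotif_env$blosum62
}

# fast char -> 1..24 encoder via a byte lookup table
aa_encoder <- function() {
  if (is.null(.lirmotif_env$enc)) {
    enc <- integer(256)
    enc[utf8ToInt(paste(lir_alphabet(), collapse = ""))] <- seq_len(24L)
    .lirmotif_env$enc <- enc
  }
  .lirmotif_env$enc
}

# Encode a vector of equal-length strings as an integer matrix
# (one row per string, one column per position). Errors on characters
# outside the alphabet.
aa_encode <- function(x, width = NULL) {
  enc <- aa_encoder()
  n <- length(x)
  if (n == 0L) return(matrix(integer(0), nrow = 0, ncol = width %||% 0))
  w <- unique(nchar(x))
  if (length(w) != 1L) stop("all sequences must have equal length")
  if (!is.null(width) && w != width) {
    stop("sequences have length ", w, ", expected ", width)
  }
  codes <- enc[utf8ToInt(paste(x, collapse = ""))]
  if (anyNA(codes) || any(codes == 0L)) {
    bad <- which(codes == 0L | is.na(codes))[1]
    stop("illegal character at string ", (bad - 1L) %/% w + 1L,
         ", position ", (bad - 1L) %% w + 1L)
  }
  matrix(codes, nrow = n, ncol = w, byrow = TRUE)
}

# validate one protein sequence; '*' is reserved for window padding
validate_sequence <- function(sequence, accession = "?") {
  if (is.na(sequence) || !nzchar(sequence)) {
    stop("empty sequence for accession '", accession, "'")
  }
  allowed <- setdiff(lir_alphabet(), "*")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% allowed)
  if (length(bad) > 0) {
    stop("illegal character '", chars[bad[1]], "' at offset ", bad[1],
         " in sequence of accession '", accession, "'")
  }
  invisible(TRUE)
}
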