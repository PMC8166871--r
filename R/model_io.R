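# Model persistence: one human-diffable JSON document holding the 300 unique
# matrix entries (keyed "AB"), the 18 position weights, the reference
# windows, and - when fitted - the score calibration and pair density.

MODEL_FORMAT_VERSION <- 1L

#' Save a model (and optional calibration / pair density) as JSON
#'
#' The substitution matrix is stored as its 300 unique upper-triangle
#' entries keyed by character pair, weights as an 18-array, and numeric
#' values at full precision, so `load_model(save_model(m))` reproduces the
#' model bit-exactly.
#'
#' @param model A [lir_model()].
#' @param path Output path.
#' @param calibration Optional [lir_calibration()].
#' @param density Optional [lam_density()].
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, calibration = NULL, density = NULL) {
  stopifnot(inherits(model, "lir_model"))
  ab <- lir_alphabet()
  pairs <- matrix_pairs()
  entries <- stats::setNames(
    as.list(model$matrix[pairs]),
    paste0(ab[pairs[, 1]], ab[pairs[, 2]])
  )
  doc <- list(
    format_version = MODEL_FORMAT_VERSION,
    origin = model$origin,
    seed = model$seed,
    weights = model$weights,
    matrix_entries = entries,
    reference = model$reference
  )
  if (!is.null(calibration)) {
    stopifnot(inherits(calibration, "lir_calibration"))
    doc$calibration <- unclass(calibration)
  }
  if (!is.null(density)) {
    stopifnot(inherits(density, "lam_density"))
    doc$pair_density <- list(x = density$points[, 1],
                             y = density$points[, 2],
                             h = density$h)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path Path to the JSON document.
#' @return A list with `model`, and `calibration` / `density` when present
#'   (otherwise `NULL`).
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("cannot parse model file '", path, "': ",
                         conditionMessage(e))
                  })
  if (is.null(doc$format_version) ||
      doc$format_version != MODEL_FORMAT_VERSION) {
    stop("model file version ", doc$format_version %||% "<missing>",
         " does not match supported version ", MODEL_FORMAT_VERSION)
  }
  ab <- lir_alphabet()
  pairs <- matrix_pairs()
  keys <- paste0(ab[pairs[, 1]], ab[pairs[, 2]])
  if (!all(keys %in% names(doc$matrix_entries))) {
    stop("model file is missing matrix entries (truncated?)")
  }
  m <- matrix(0, 24, 24, dimnames = list(ab, ab))
  vals <- unlist(doc$matrix_entries[keys])
  m[pairs] <- vals
  m[pairs[, 2:1, drop = FALSE]] <- vals
  model <- lir_model(tibble::as_tibble(doc$reference), matrix = m,
                     weights = doc$weights, seed = doc$seed,
                     origin = doc$origin)
  calibration <- NULL
  if (!is.null(doc$calibration)) {
    cc <- doc$calibration
    calibration <- lir_calibration(cc$pos_points, cc$neg_points,
                                   cc$h_pos, cc$h_neg, cc$prior_pos,
                                   cc$scale_min, cc$scale_max)
  }
  density <- NULL
  if (!is.null(doc$pair_density)) {
    density <- lam_density(cbind(doc$pair_density$x, doc$pair_density$y),
                           doc$pair_density$h)
  }
  list(model = model, calibration = calibration, density = density)
}
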