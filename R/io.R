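#' Read a response + predictor dataset
#'
#' Reads a CSV (or TSV, by file extension) with a header whose `y` column is
#' the binary response and whose remaining columns are numeric predictors.
#' Missing or non-numeric cells are rejected with the offending row and
#' column named.
#'
#' @param path File path; `.tsv`/`.tab` extensions are read as
#'   tab-separated, anything else as comma-separated.
#' @param response Name of the response column (default `"y"`).
#' @return A list with `x` (numeric matrix, original column names) and `y`
#'   (numeric vector).
#' @export
read_dataset <- function(path, response = "y") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- if (grepl("\\.(tsv|tab)$", path)) "\t" else ","
  data <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_double()),
    progress = FALSE
  )
  if (!response %in% names(data)) {
    abort(sprintf("column `%s` not found in %s", response, path))
  }
  if (nrow(data) < 2) abort("dataset must have at least 2 rows")
  bad <- which(is.na(as.matrix(data)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "missing or non-numeric value at row %d, column `%s`",
      bad[1, "row"], names(data)[bad[1, "col"]]
    ))
  }
  xy <- split_response(data, response)
  list(x = xy$x, y = xy$y)
}

#' Write a simulated dataset to CSV
#'
#' Writes the observed data table (column `y` then predictors `"1"..."p"`)
#' and, optionally alongside it, the misclassification probabilities as a
#' two-column CSV (`pi10`, `pi01`).  Both files round-trip through
#' [read_dataset()] / [readr::read_csv()] at full precision.
#'
#' @param sim An `"me_sim"` object from [simulate_me_binary()].
#' @param path Output CSV path for the data table.
#' @param probs_path Optional output path for the probabilities.
#' @return `path`, invisibly.
#' @export
write_sim <- function(sim, path, probs_path = NULL) {
  if (!inherits(sim, "me_sim")) abort("`sim` must be an `me_sim` object")
  readr::write_csv(sim$data, path, progress = FALSE)
  if (!is.null(probs_path)) {
    readr::write_csv(sim$probs, probs_path, progress = FALSE)
  }
  invisible(path)
}

#' Standardize predictor columns
#'
#' Centres each column to mean 0 and scales it to variance 1 using the
#' population (denominator n) standard deviation, the convention of the
#' usual z-score preprocessing step applied before fitting.  Note the
#' regression-calibration covariance ([regression_calibration()]) uses the
#' n - 1 denominator; the two conventions are deliberate and documented.
#'
#' @param x Numeric predictor matrix or data frame of predictors.
#' @return A matrix of the same shape.  A constant column is an error (its
#'   name or index is reported).
#' @examples
#' standardize(matrix(c(0, 2, 4), 3))  # -1.2247, 0, 1.2247
#' @export
standardize <- function(x) {
  x <- as_predictor_matrix(x)
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2, mu)^2))
  if (any(sdev == 0)) {
    j <- which(sdev == 0)[1]
    abort(sprintf(
      "constant predictor column `%s` cannot be standardized",
      colnames(x)[j] %||% as.character(j)
    ))
  }
  sweep(sweep(x, 2, mu), 2, sdev, `/`)
}
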