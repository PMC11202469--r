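#' Read a single-column series from a text file
#'
#' One decimal value per line; a single-column CSV is tolerated and a
#' non-numeric header line is skipped automatically.  Parsing failures
#' are reported with their 1-based line number.
#'
#' @param path Path to the file.
#' @return Numeric vector of finite values.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stop(sprintf("empty file: %s", path))
  line_no <- which(keep)
  fields <- strsplit(trimws(lines[keep]), ",", fixed = TRUE)
  multi <- vapply(fields, function(f) sum(nzchar(trimws(f))) > 1L, logical(1))
  if (any(multi))
    stop(sprintf("expected a single column but found several fields on line %d",
                 line_no[which(multi)[1L]]))
  first <- vapply(fields, function(f) trimws(f[1L]), character(1))
  vals <- suppressWarnings(as.numeric(first))
  bad <- which(!is.finite(vals))
  # a lone unparsable first line is treated as a header
  if (length(bad) && bad[1L] == 1L && length(vals) > 1L &&
      all(is.finite(vals[-1L]))) {
    vals <- vals[-1L]
    bad <- integer(0)
  }
  if (length(bad))
    stop(sprintf("cannot parse '%s' as a number on line %d",
                 first[bad[1L]], line_no[bad[1L]]))
  if (length(vals) < 1L) stop(sprintf("no data rows in %s", path))
  vals
}

#' Write a series to a text file, one sample per line
#'
#' Values are printed with 17 significant digits so that a write/read
#' round trip reproduces the doubles exactly.
#'
#' @param x Numeric vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) {
  writeLines(sprintf("%.17g", x), path)
  invisible(path)
}

#' Write plane curves as tidy TSV
#'
#' Columns `scale`, `q`, `Hq`, `Cq`, one row per scale and grid point,
#' printed with 12 significant digits.
#'
#' @param curves A `plane_curve`, a list of them, or a
#'   `multiscale_features` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_tsv <- function(curves, path) {
  if (inherits(curves, "multiscale_features")) curves <- curves$curves
  if (inherits(curves, "plane_curve")) curves <- list(curves)
  tall <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(scale = attr(cv, "scale") %||% NA_integer_,
               q = cv$q, Hq = cv$Hq, Cq = cv$Cq)
  }))
  fmt <- function(v) sprintf("%.12g", v)
  out <- data.frame(scale = tall$scale, q = fmt(tall$q),
                    Hq = fmt(tall$Hq), Cq = fmt(tall$Cq))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write plane features as JSON
#'
#' One object per scale with fields `scale`, `q_H_star`, `q_C_star`,
#' `H_min`, `C_max`, plus a `config` block echoing the run parameters
#' for reproducibility.
#'
#' @param features A `plane_features` data frame (any number of rows) or
#'   a `multiscale_features` object.
#' @param path Output path.
#' @param config Optional named list echoed into the output.
#' @return `path`, invisibly.
#' @export
write_features_json <- function(features, path, config = NULL) {
  if (inherits(features, "multiscale_features")) features <- features$features
  payload <- list(features = features)
  if (!is.null(config)) payload$config <- config
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
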