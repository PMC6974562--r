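#' A single replicate's density (or fluorescence) time series
#'
#' Light container for one flask-and-species trajectory: strictly increasing
#' sampling times in hours paired with nonnegative population densities
#' (cells per ml) or, for plate-reader data, relative fluorescence units.
#' All growth-rate estimators accept these objects (or anything coercible
#' via [as_density_series()]).
#'
#' @param time_h numeric vector of sampling times in hours, strictly
#'   increasing, at least two values.
#' @param value numeric vector of the same length: densities in cells per ml
#'   (or fluorescence in RFU), nonnegative and finite.
#' @param species,treatment,role,flask_id,replicate optional annotations
#'   carried through to fit tables.
#' @param measurement `"density"` (hemocytometer counts) or
#'   `"fluorescence"` (chlorophyll-a proxy).  Fluorescence-derived rate
#'   estimates are flagged and refused by the sensitivity layer by default,
#'   because fluorescence responds to cell properties beyond density.
#' @return an object of class `density_series`.
#' @examples
#' s <- density_series(c(0, 19, 26), 1000 * exp(0.1 * c(0, 19, 26)))
#' easylinear_rate(s, h = 3)
#' @export
density_series <- function(time_h, value, species = NA_character_,
                           treatment = NA_character_, role = NA_character_,
                           flask_id = NA_character_, replicate = NA_integer_,
                           measurement = c("density", "fluorescence")) {
  measurement <- match.arg(measurement)
  if (!is.numeric(time_h) || !is.numeric(value))
    stop("'time_h' and 'value' must be numeric", call. = FALSE)
  if (length(time_h) != length(value))
    stop("'time_h' and 'value' must have equal length", call. = FALSE)
  if (length(time_h) < 2L)
    stop("a density series needs at least 2 observations", call. = FALSE)
  if (anyNA(time_h) || any(!is.finite(time_h)))
    stop("'time_h' contains non-finite values", call. = FALSE)
  if (any(diff(time_h) <= 0))
    stop("'time_h' must be strictly increasing", call. = FALSE)
  if (anyNA(value) || any(!is.finite(value)))
    stop("'value' contains non-finite values", call. = FALSE)
  if (any(value < 0))
    stop("densities must be nonnegative", call. = FALSE)
  structure(
    list(time_h = as.numeric(time_h), value = as.numeric(value),
         species = species, treatment = treatment, role = role,
         flask_id = flask_id, replicate = replicate,
         measurement = measurement),
    class = "density_series"
  )
}

#' Coerce to a density series
#'
#' @param x a `density_series`, a list with `time_h`/`value` elements, or a
#'   data frame with `time_h` and `density_cells_per_ml` (or
#'   `fluorescence_rfu`) columns, e.g. one flask-and-species subset of
#'   [generate_experiment()] output.
#' @param ... passed to [density_series()].
#' @return a `density_series`.
#' @export
as_density_series <- function(x, ...) UseMethod("as_density_series")

#' @export
as_density_series.density_series <- function(x, ...) x

#' @export
as_density_series.data.frame <- function(x, ...) {
  args <- list(...)
  measurement <- args$measurement %||% "density"
  value_col <- if (measurement == "fluorescence") "fluorescence_rfu"
               else "density_cells_per_ml"
  if (!all(c("time_h", value_col) %in% names(x)))
    stop(sprintf("data frame needs columns 'time_h' and '%s'", value_col),
         call. = FALSE)
  x <- x[order(x$time_h), , drop = FALSE]
  first <- function(col) if (col %in% names(x)) x[[col]][1L] else NA
  density_series(
    x$time_h, x[[value_col]],
    species = as.character(first("species")),
    treatment = as.character(first("treatment")),
    role = as.character(first("role")),
    flask_id = as.character(first("flask_id")),
    replicate = if ("replicate" %in% names(x)) as.integer(x$replicate[1L])
                else NA_integer_,
    measurement = measurement
  )
}

#' @export
as_density_series.list <- function(x, ...) {
  if (is.null(x$time_h) || is.null(x$value))
    stop("list must contain 'time_h' and 'value'", call. = FALSE)
  do.call(density_series, c(x, list(...)))
}

#' @export
print.density_series <- function(x, ...) {
  cat(sprintf("<density_series> %s obs, %s [%s]\n",
              length(x$time_h), x$measurement,
              paste(stats::na.omit(c(x$flask_id, x$species)), collapse = " ")))
  print(data.frame(time_h = x$time_h, value = x$value), row.names = FALSE)
  invisible(x)
}
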