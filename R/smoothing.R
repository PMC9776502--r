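#' Two-pass moving-average smoothing of a scalar sequence
#'
#' Applies two successive centered moving averages to the mapped scalar
#' relationship sequence: an internal pass with radius `r_internal`
#' followed by an external pass with radius `r_external`. A pass with
#' radius r replaces each value by the mean over the window
#' `[i - r, i + r]`; near the sequence ends the window shrinks
#' symmetrically (radius `min(r, i - 1, n - i)`), so the output has the
#' same length as the input and constant sequences pass through
#' unchanged. Radius 0 is the identity for that pass.
#'
#' @param x Numeric vector, or a `relationship_series` whose `values`
#'   are smoothed in place (its `smoothing` field is updated).
#' @param r_internal,r_external Non-negative integer radii in samples.
#'   Defaults 2 and 10.
#' @return Same shape as the input: a numeric vector, or the updated
#'   `relationship_series`.
#' @examples
#' smooth_series(c(0, 1, 0, 1, 0, 1), r_internal = 1, r_external = 0)
#' @export
smooth_series <- function(x, r_internal = 2, r_external = 10) {
  if (inherits(x, "relationship_series")) {
    x$values <- smooth_series(x$values, r_internal, r_external)
    x$smoothing <- c(r_internal = as.integer(r_internal),
                     r_external = as.integer(r_external))
    return(x)
  }
  x <- as.numeric(x)
  if (length(x) == 0) stop("cannot smooth an empty sequence")
  if (anyNA(x)) stop("cannot smooth a sequence containing NA")
  r_internal <- as.integer(r_internal); r_external <- as.integer(r_external)
  if (r_internal < 0 || r_external < 0) stop("smoothing radii must be >= 0")
  moving_average_pass(moving_average_pass(x, r_internal), r_external)
}

# centered moving average, window shrinking symmetrically at the ends
moving_average_pass <- function(x, r) {
  n <- length(x)
  if (r == 0 || n == 1) return(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  ri <- pmin(r, i - 1L, n - i)          # effective radius per position
  (cs[i + ri + 1L] - cs[i - ri]) / (2 * ri + 1)
}

#' Summary statistics and one-sigma band of a smoothed sequence
#'
#' Computes the variance, mean, median and standard deviation of a
#' smoothed relationship sequence together with the one-sigma band
#' around the median: upper limit `median + sd`, lower limit
#' `median - sd`. These are the per-subject descriptors used to compare
#' parameter orderings and, through the variance, to build the cohort
#' baseline.
#'
#' @param x Numeric vector (typically the output of [smooth_series()])
#'   or a `relationship_series`.
#' @param variance_mode `"sample"` (n - 1 denominator, default) or
#'   `"population"` (n).
#' @return A list of class `sequence_summary` with fields `variance`,
#'   `mean`, `median`, `std`, `upper_limit`, `lower_limit`, `n` and
#'   `area` (`NA` until [excursion_area()] is attached by a caller).
#' @export
summarize_sequence <- function(x, variance_mode = c("sample", "population")) {
  variance_mode <- match.arg(variance_mode)
  if (inherits(x, "relationship_series")) x <- x$values
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) stop("need at least 2 values to summarize a sequence")
  v <- stats::var(x)
  if (variance_mode == "population") v <- v * (n - 1) / n
  s <- sqrt(v)
  med <- stats::median(x)
  structure(list(variance = v, mean = mean(x), median = med, std = s,
                 upper_limit = med + s, lower_limit = med - s,
                 n = n, area = NA_real_,
                 variance_mode = variance_mode),
            class = "sequence_summary")
}

#' @export
print.sequence_summary <- function(x, ...) {
  cat(sprintf(
    "<sequence_summary> n=%d  var=%.4g  mean=%.4g  median=%.4g  sd=%.4g\n",
    x$n, x$variance, x$mean, x$median, x$std))
  cat(sprintf("  one-sigma band [%.4g, %.4g]  area=%s\n",
              x$lower_limit, x$upper_limit,
              if (is.na(x$area)) "NA" else sprintf("%.4g", x$area)))
  invisible(x)
}

#' Signed excursion area outside a one-sigma band
#'
#' Accumulates the area of the smoothed sequence outside the band: where
#' the sequence exceeds the upper limit the overshoot is added, where it
#' drops below the lower limit the (negative) undershoot is added, so
#' below-band excursions contribute negatively and a sequence that stays
#' inside the band has area zero.
#'
#' @param x Numeric sequence (or `relationship_series`).
#' @param upper,lower Band limits, `lower <= upper`.
#' @param dt Sample spacing used as the width of each rectangle;
#'   default 1 (one beat). Pass the mean beat spacing in minutes to get
#'   the area on the physical time axis.
#' @return Signed area A.
#' @examples
#' excursion_area(c(2, 2), upper = 1, lower = 0)   #  2
#' excursion_area(c(-1, -1), upper = 1, lower = 0) # -2
#' @export
excursion_area <- function(x, upper, lower, dt = 1) {
  if (inherits(x, "relationship_series")) x <- x$values
  x <- as.numeric(x)
  if (length(x) == 0) stop("empty sequence")
  if (!is.finite(upper) || !is.finite(lower) || lower > upper)
    stop("band limits must be finite with lower <= upper")
  if (dt <= 0) stop("dt must be positive")
  dt * (sum(pmax(x - upper, 0)) - sum(pmax(lower - x, 0)))
}

#' Full per-subject summary row: map, smooth, summarize, area
#'
#' Convenience composition of the whole per-subject pipeline: build the
#' relationship sequence, smooth it, summarize it, and attach the signed
#' excursion area outside the subject's own one-sigma band.
#'
#' @inheritParams relationship_series
#' @param r_internal,r_external Smoothing radii, see [smooth_series()].
#' @param variance_mode See [summarize_sequence()].
#' @param dt Sample spacing for the area, see [excursion_area()].
#' @return A `sequence_summary` with the `area` field filled in.
#' @export
subject_summary <- function(series, delta = 1, order = 3,
                            variable_order = c("jt", "qrs", "rr"),
                            mapping = "frobenius_norm",
                            r_internal = 2, r_external = 10,
                            variance_mode = "sample", dt = 1) {
  rel <- relationship_series(series, delta, order, variable_order, mapping)
  sm <- smooth_series(rel, r_internal, r_external)
  out <- summarize_sequence(sm, variance_mode)
  out$area <- excursion_area(sm, out$upper_limit, out$lower_limit, dt)
  out
}
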