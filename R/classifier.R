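#' Probability indicator of a candidate within the variation interval
#'
#' Places a new candidate's variance value C inside the one-sigma
#' variation interval and returns the indicator IND together with the
#' condition that fired:
#' \itemize{
#'   \item Condition 1: `C <= left` -> `IND = 0` (healthy side);
#'   \item Condition 2: `C >= right` -> `IND = 1` (unhealthy side);
#'   \item Condition 3: otherwise `IND = (C - left) / (right - left)`,
#'     the candidate's linear position within the interval.
#' }
#' IND is read as the likelihood of an atrial-fibrillation indication.
#'
#' The default anchors the linear form at `left = mu_h - sigma_h` and
#' `right = mu_uh + sigma_uh`, the same boundaries that define the
#' interval; this reproduces the reference worked examples (0.07 and
#' 0.54). `formula = "transposed"` instead anchors at
#' `mu_uh - sigma_uh` and `mu_h + sigma_h`, i.e. with the cohort roles
#' of the inner anchors swapped — a variant kept only for comparison, it
#' is not consistent with the interval boundaries.
#'
#' @param C Candidate variance value (variance of the candidate's
#'   smoothed relationship sequence).
#' @param iv A [variation_interval()].
#' @param formula `"interval"` (default) or `"transposed"`.
#' @return List with `ind` (clipped to `[0, 1]`) and `condition`
#'   (1, 2 or 3).
#' @examples
#' iv <- reference_baseline()
#' indicator(0.0018, iv)$ind  # ~0.07
#' indicator(0.0040, iv)$ind  # ~0.54
#' @export
indicator <- function(C, iv, formula = c("interval", "transposed")) {
  formula <- match.arg(formula)
  stopifnot(inherits(iv, "variation_interval"))
  if (!iv$valid || iv$left >= iv$right)
    stop("cannot classify against a degenerate variation interval")
  C <- as.numeric(C)
  stopifnot(length(C) == 1, is.finite(C))
  if (C <= iv$left) return(list(ind = 0, condition = 1L))
  if (C >= iv$right) return(list(ind = 1, condition = 2L))
  anchors <- if (formula == "interval") {
    c(iv$left, iv$right)
  } else {
    h <- iv$source_fits$healthy; uh <- iv$source_fits$unhealthy
    c(uh$mu - uh$sigma, h$mu + h$sigma)
  }
  if (anchors[1] >= anchors[2])
    stop("degenerate indicator anchors under formula '", formula, "'")
  ind <- (C - anchors[1]) / (anchors[2] - anchors[1])
  list(ind = min(max(ind, 0), 1), condition = 3L)
}

#' Classify a candidate and assign a semi-gauge color
#'
#' Maps the indicator to the traffic-light color of the semi-gauge
#' warning tool: green for `IND <= green_max`, red for
#' `IND >= red_min`, yellow in between. The defaults (`green_max = 1/3`,
#' `red_min = 1`) put a low-likelihood candidate (e.g. IND 0.07) in
#' green, an intermediate one (e.g. IND 0.54) in yellow, and reserve red
#' for candidates at or beyond the right interval boundary.
#'
#' @inheritParams indicator
#' @param green_max Upper IND bound for green (default 1/3).
#' @param red_min Lower IND bound for red (default 1).
#' @return A `classification_result`: `candidate_value`, `ind`,
#'   `condition`, `color`, `thresholds`, `interval_used`.
#' @examples
#' classify(0.0018, reference_baseline())$color  # "green"
#' @export
classify <- function(C, iv, green_max = 1 / 3, red_min = 1,
                     formula = c("interval", "transposed")) {
  if (!(is.numeric(green_max) && is.numeric(red_min) &&
        green_max >= 0 && green_max < red_min && red_min <= 1))
    stop("thresholds must satisfy 0 <= green_max < red_min <= 1")
  r <- indicator(C, iv, formula)
  color <- if (r$ind <= green_max) "green"
           else if (r$ind >= red_min) "red"
           else "yellow"
  structure(list(candidate_value = as.numeric(C), ind = r$ind,
                 condition = r$condition, color = color,
                 thresholds = c(green_max = green_max, red_min = red_min),
                 interval_used = c(left = iv$left, right = iv$right)),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(
    "<classification_result> C=%.6g  IND=%.2f  condition %d  -> %s\n",
    x$candidate_value, x$ind, x$condition, toupper(x$color)))
  cat(sprintf("  variation interval [%.6g, %.6g]\n",
              x$interval_used["left"], x$interval_used["right"]))
  invisible(x)
}

#' Machine-readable semi-gauge report
#'
#' Renders a classification as the data behind the semi-gauge dial: the
#' needle fraction equals IND exactly (0 = far left/green end, 1 = far
#' right end), plus the color, condition and interval bounds. The report
#' round-trips through JSON.
#'
#' @param result A `classification_result`.
#' @param path Optional path; when given the report is also written as
#'   JSON.
#' @return A list of class `gauge_report`.
#' @export
gauge_report <- function(result, path = NULL) {
  stopifnot(inherits(result, "classification_result"))
  rep <- structure(list(
    needle_fraction = result$ind,
    color = result$color,
    condition = result$condition,
    candidate_value = result$candidate_value,
    interval = list(left = unname(result$interval_used["left"]),
                    right = unname(result$interval_used["right"])),
    thresholds = list(
      green_max = unname(result$thresholds["green_max"]),
      red_min = unname(result$thresholds["red_min"]))),
    class = "gauge_report")
  if (!is.null(path))
    jsonlite::write_json(unclass(rep), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  rep
}

#' Read a gauge report back from JSON
#' @param path JSON path written by [gauge_report()].
#' @return A `gauge_report` list.
#' @export
read_gauge_report <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "gauge_report")
}
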