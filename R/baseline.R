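#' Gaussian fit of per-subject variances for one cohort
#'
#' Fits a normal model to the per-subject variance values of one cohort
#' (healthy or unhealthy): arithmetic mean, sample (n - 1) standard
#' deviation, normal-theory 95% confidence intervals (t interval for the
#' mean, chi-square interval for the standard deviation), and an
#' Anderson-Darling goodness-of-fit test of normality at the 5% level.
#'
#' A cohort of identical values has zero spread; the fit is then flagged
#' `degenerate` and the normality test is reported as rejected since no
#' Gaussian model is identifiable.
#'
#' @param values Numeric vector of per-subject variances (>= 3 values,
#'   all non-negative).
#' @param label Cohort label, `"healthy"` or `"unhealthy"`.
#' @param conf_level Confidence level for the intervals, default 0.95.
#' @return An object of class `cohort_fit`: `label`, `values`, `n`,
#'   `mu`, `sigma`, `ci95_mu`, `ci95_sigma`, `ad_statistic`, `ad_p`,
#'   `ad_normal_at_5pct`, `degenerate`.
#' @examples
#' fit_cohort(c(0.0012, 0.0030, 0.0023, 0.0014,
#'              0.0040, 0.0025, 0.0031, 0.0018), "healthy")
#' @export
fit_cohort <- function(values, label = c("healthy", "unhealthy"),
                       conf_level = 0.95) {
  label <- match.arg(label)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) stop("need at least 3 variance values to fit a cohort, got ", n)
  if (anyNA(values) || any(values < 0))
    stop("variance values must be non-negative and non-missing")
  mu <- mean(values)
  sigma <- stats::sd(values)
  alpha <- 1 - conf_level
  degenerate <- sigma == 0
  if (degenerate) {
    ci_mu <- c(mu, mu)
    ci_sigma <- c(0, 0)
    ad_stat <- NA_real_; ad_p <- NA_real_; ad_ok <- FALSE
  } else {
    tq <- stats::qt(1 - alpha / 2, df = n - 1)
    ci_mu <- mu + c(-1, 1) * tq * sigma / sqrt(n)
    ci_sigma <- sigma * sqrt((n - 1) /
      stats::qchisq(c(1 - alpha / 2, alpha / 2), df = n - 1))
    ad <- ad_normality_test(values)
    ad_stat <- ad$statistic; ad_p <- ad$p_value
    ad_ok <- ad_p > 0.05
  }
  structure(list(label = label, values = values, n = n,
                 mu = mu, sigma = sigma,
                 ci95_mu = ci_mu, ci95_sigma = ci_sigma,
                 ad_statistic = ad_stat, ad_p = ad_p,
                 ad_normal_at_5pct = ad_ok,
                 degenerate = degenerate,
                 conf_level = conf_level),
            class = "cohort_fit")
}

#' @export
print.cohort_fit <- function(x, ...) {
  cat(sprintf("<cohort_fit> %s: n=%d  mu=%.6g  sigma=%.6g%s\n",
              x$label, x$n, x$mu, x$sigma,
              if (x$degenerate) "  [degenerate]" else ""))
  cat(sprintf("  95%% CI mu [%.6g, %.6g], sigma [%.6g, %.6g]\n",
              x$ci95_mu[1], x$ci95_mu[2], x$ci95_sigma[1], x$ci95_sigma[2]))
  if (!is.na(x$ad_statistic))
    cat(sprintf("  Anderson-Darling A=%.4f p=%.3f -> normality %s at 5%%\n",
                x$ad_statistic, x$ad_p,
                if (x$ad_normal_at_5pct) "accepted" else "rejected"))
  invisible(x)
}

#' One-sigma variation interval spanning the two cohort Gaussians
#'
#' The classification window runs from the left boundary
#' `mu_h - sigma_h` of the healthy fit to the right boundary
#' `mu_uh + sigma_uh` of the unhealthy fit. A candidate's position inside
#' this interval drives the probability indicator. If the boundaries are
#' inverted (left >= right) the interval is returned with `valid = FALSE`
#' and a warning — classification on such an interval errors rather than
#' silently proceeding.
#'
#' @param h `cohort_fit` of the healthy cohort.
#' @param uh `cohort_fit` of the unhealthy cohort.
#' @return A `variation_interval` with `left`, `right`, `valid` and
#'   `source_fits`.
#' @export
variation_interval <- function(h, uh) {
  stopifnot(inherits(h, "cohort_fit"), inherits(uh, "cohort_fit"))
  left <- h$mu - h$sigma
  right <- uh$mu + uh$sigma
  valid <- left < right
  if (!valid)
    warning("degenerate variation interval: left boundary (", left,
            ") is not below the right boundary (", right, ")")
  structure(list(left = left, right = right, valid = valid,
                 source_fits = list(healthy = h, unhealthy = uh)),
            class = "variation_interval")
}

#' @export
print.variation_interval <- function(x, ...) {
  cat(sprintf("<variation_interval> [%.6g, %.6g]%s\n", x$left, x$right,
              if (x$valid) "" else "  [INVALID: left >= right]"))
  invisible(x)
}

#' Reference AF screening baseline shipped with the package
#'
#' Loads the per-subject variance values of the package's reference
#' cohorts (8 healthy, 7 AF) from the bundled CSV, fits both cohort
#' Gaussians and returns the resulting variation interval. This is the
#' default baseline used by the classifier when no cohort of your own is
#' supplied.
#'
#' @param path Optional path to a two-column CSV (`cohort`, `variance`)
#'   with cohort labels `healthy` / `unhealthy`; defaults to the bundled
#'   reference file.
#' @return A `variation_interval` (its `source_fits` carry both
#'   `cohort_fit`s).
#' @examples
#' iv <- reference_baseline()
#' c(iv$left, iv$right)
#' @export
reference_baseline <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reference_variances.csv",
                        package = "pmold", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("cohort", "variance") %in% names(df)))
    stop("baseline CSV needs columns 'cohort' and 'variance'")
  lab <- tolower(df$cohort)
  if (!all(lab %in% c("healthy", "unhealthy")))
    stop("cohort labels must be 'healthy' or 'unhealthy'")
  h <- fit_cohort(df$variance[lab == "healthy"], "healthy")
  uh <- fit_cohort(df$variance[lab == "unhealthy"], "unhealthy")
  variation_interval(h, uh)
}

#' Serialize a variation interval (with its fits) to JSON
#'
#' Writes the interval boundaries, both cohort fits (inputs, estimates,
#' confidence intervals, normality test) and the package version so a
#' baseline can be archived and re-used for later classifications.
#'
#' @param iv A `variation_interval`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_baseline <- function(iv, path) {
  stopifnot(inherits(iv, "variation_interval"))
  fit_block <- function(f) list(
    label = f$label, n = f$n, values = f$values, mu = f$mu,
    sigma = f$sigma, ci95_mu = f$ci95_mu, ci95_sigma = f$ci95_sigma,
    ad_statistic = f$ad_statistic, ad_p = f$ad_p,
    ad_normal_at_5pct = f$ad_normal_at_5pct, degenerate = f$degenerate)
  obj <- list(
    left = iv$left, right = iv$right, valid = iv$valid,
    estimator = "sample_sd",
    healthy = fit_block(iv$source_fits$healthy),
    unhealthy = fit_block(iv$source_fits$unhealthy),
    package = "pmold",
    version = as.character(utils::packageVersion("pmold")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a baseline JSON written by [write_baseline()]
#' @param path JSON path.
#' @return A `variation_interval`.
#' @export
read_baseline <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  h <- fit_cohort(obj$healthy$values, "healthy")
  uh <- fit_cohort(obj$unhealthy$values, "unhealthy")
  variation_interval(h, uh)
}
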