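#' Parameters of one synthetic subject
#'
#' Describes the generative model of one synthetic subject's beat-wise
#' intervals. RR follows a stationary AR(1) process around `rr_mean`
#' with marginal standard deviation `rr_sd` and lag-one autocorrelation
#' `rr_autocorr`. Healthy sinus rhythm is emulated with strong
#' autocorrelation and a small spread; AF-like rhythm ("irregularly
#' irregular") with near-zero autocorrelation and a spread several times
#' larger. JT is coupled to RR through a square-root law
#' `jt = jt_intercept + jt_slope * sqrt(rr) + noise` (rate-dependent
#' repolarization, Bazett-style), and QRS is independent Gaussian — its
#' duration does not track the beat period in either group.
#'
#' @param group `"healthy"` or `"af_like"`; selects the default
#'   parameter block, any field of which can be overridden.
#' @param n_beats Number of beats (default 2000, roughly a half-hour
#'   recording at 0.9 s per beat).
#' @param rr_mean,rr_sd Marginal mean / sd of RR in seconds.
#' @param rr_autocorr AR(1) coefficient in `[0, 1)`.
#' @param jt_intercept,jt_slope,jt_noise_sd JT coupling coefficients
#'   (seconds; slope in s per sqrt-s).
#' @param qrs_mean,qrs_sd QRS duration mean / sd in seconds.
#' @param seed Integer seed; the subject is fully reproducible from it.
#' @return A list of class `subject_params`.
#' @export
subject_params <- function(group = c("healthy", "af_like"),
                           n_beats = 2000,
                           rr_mean = NULL, rr_sd = NULL,
                           rr_autocorr = NULL,
                           jt_intercept = 0.02, jt_slope = 0.30,
                           jt_noise_sd = NULL,
                           qrs_mean = 0.09, qrs_sd = NULL,
                           seed = 1L) {
  group <- match.arg(group)
  def <- if (group == "healthy") {
    list(rr_mean = 0.90, rr_sd = 0.035, rr_autocorr = 0.8,
         jt_noise_sd = 0.006, qrs_sd = 0.005)
  } else {
    list(rr_mean = 0.85, rr_sd = 0.12, rr_autocorr = 0.1,
         jt_noise_sd = 0.010, qrs_sd = 0.008)
  }
  p <- list(group = group, n_beats = as.integer(n_beats),
            rr_mean = rr_mean %||% def$rr_mean,
            rr_sd = rr_sd %||% def$rr_sd,
            rr_autocorr = rr_autocorr %||% def$rr_autocorr,
            jt_intercept = jt_intercept, jt_slope = jt_slope,
            jt_noise_sd = jt_noise_sd %||% def$jt_noise_sd,
            qrs_mean = qrs_mean, qrs_sd = qrs_sd %||% def$qrs_sd,
            seed = as.integer(seed))
  validate_subject_params(p)
  structure(p, class = "subject_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_subject_params <- function(p) {
  if (p$n_beats < 3) stop("n_beats must be >= 3")
  if (p$rr_mean <= 0 || p$qrs_mean <= 0 || p$jt_slope <= 0)
    stop("duration parameters must be positive")
  if (p$rr_sd < 0 || p$qrs_sd < 0 || p$jt_noise_sd < 0)
    stop("noise standard deviations must be non-negative")
  if (p$rr_autocorr < 0 || p$rr_autocorr >= 1)
    stop("rr_autocorr must lie in [0, 1)")
  if (is.na(p$seed)) stop("seed must be an integer")
  invisible(p)
}

# run expr with a private RNG stream; the caller's RNG state is untouched
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

PHYSIOLOGICAL_FLOOR <- 0.02  # seconds; no real interval is shorter

#' Generate one synthetic subject's interval series
#'
#' Draws the RR series from the stationary AR(1) model (innovation sd
#' `rr_sd * sqrt(1 - rr_autocorr^2)`, so the marginal sd is `rr_sd`),
#' derives JT through the square-root coupling plus independent noise,
#' and draws QRS as independent Gaussian. All intervals are clipped at a
#' physiological floor of 0.02 s; the number of clipped values is
#' recorded in the `clipped` attribute (zero at the default parameters).
#'
#' @param p A [subject_params()] object.
#' @param subject_id Label for the generated series.
#' @return An [interval_series()] with `beat_times` (cumulative minutes)
#'   and attribute `clipped`.
#' @examples
#' s <- generate_subject(subject_params("healthy", n_beats = 100, seed = 7))
#' n_beats(s)
#' @export
generate_subject <- function(p, subject_id = NULL) {
  if (!inherits(p, "subject_params")) stop("p must be a subject_params object")
  validate_subject_params(p)
  if (is.null(subject_id))
    subject_id <- sprintf("%s_seed%d", p$group, p$seed)
  with_seed(p$seed, {
    n <- p$n_beats
    phi <- p$rr_autocorr
    innov_sd <- p$rr_sd * sqrt(1 - phi^2)
    rr <- numeric(n)
    rr[1] <- p$rr_mean + stats::rnorm(1, 0, p$rr_sd)
    if (n > 1) {
      e <- stats::rnorm(n - 1, 0, innov_sd)
      for (i in 2:n) rr[i] <- p$rr_mean + phi * (rr[i - 1] - p$rr_mean) + e[i - 1]
    }
    jt <- p$jt_intercept + p$jt_slope * sqrt(pmax(rr, PHYSIOLOGICAL_FLOOR)) +
      stats::rnorm(n, 0, p$jt_noise_sd)
    qrs <- stats::rnorm(n, p$qrs_mean, p$qrs_sd)
    clipped <- sum(rr < PHYSIOLOGICAL_FLOOR) + sum(jt < PHYSIOLOGICAL_FLOOR) +
      sum(qrs < PHYSIOLOGICAL_FLOOR)
    rr <- pmax(rr, PHYSIOLOGICAL_FLOOR)
    jt <- pmax(jt, PHYSIOLOGICAL_FLOOR)
    qrs <- pmax(qrs, PHYSIOLOGICAL_FLOOR)
    out <- interval_series(jt = jt, qrs = qrs, rr = rr,
                           subject_id = subject_id,
                           beat_times = cumsum(rr) / 60)
    attr(out, "clipped") <- clipped
    attr(out, "params") <- p
    out
  })
}

#' Generate a seeded synthetic cohort
#'
#' Derives one deterministic seed per subject from the cohort seed and
#' applies mild multiplicative between-subject jitter to the rate
#' parameters (rr_mean x U(0.93, 1.07), rr_sd x U(0.8, 1.25),
#' qrs_mean x U(0.95, 1.05)) so subjects differ while remaining within
#' their group's regime.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param group `"healthy"` or `"af_like"`.
#' @param base_params Optional [subject_params()] whose non-seed fields
#'   serve as the cohort template; defaults to the group defaults.
#' @param seed Cohort seed (integer).
#' @param n_beats Beats per subject; overrides the template when given.
#' @return A list of [interval_series()], one per subject, named
#'   `<group>_01`, `<group>_02`, ...
#' @export
generate_cohort <- function(n_subjects, group = c("healthy", "af_like"),
                            base_params = NULL, seed = 1L,
                            n_beats = NULL) {
  group <- match.arg(group)
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  base <- base_params %||% subject_params(group)
  if (!is.null(n_beats)) base$n_beats <- as.integer(n_beats)
  out <- lapply(seq_len(n_subjects), function(i) {
    sseed <- subject_seed(seed, i)
    jitter <- with_seed(sseed + 1L, stats::runif(3))
    p <- base
    p$group <- group
    p$seed <- sseed
    p$rr_mean <- base$rr_mean * (0.93 + 0.14 * jitter[1])
    p$rr_sd <- base$rr_sd * (0.80 + 0.45 * jitter[2])
    p$qrs_mean <- base$qrs_mean * (0.95 + 0.10 * jitter[3])
    class(p) <- "subject_params"
    generate_subject(p, subject_id = sprintf("%s_%02d", group, i))
  })
  names(out) <- vapply(out, function(s) s$subject_id, character(1))
  out
}

# deterministic per-subject seed, kept inside the 32-bit integer range
subject_seed <- function(cohort_seed, index) {
  as.integer((as.numeric(cohort_seed) * 48271 + index * 30269) %% 2147483629)
}
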