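#' Beat-wise cardiac interval series for one subject
#'
#' Bundles the three aligned beat-wise interval sequences of one subject:
#' the JT interval (ventricular repolarization), the QRS duration
#' (ventricular depolarization) and the RR interval (inter-beat period),
#' one value per heartbeat, all in seconds.
#'
#' @param jt Numeric vector of JT intervals in seconds, one per beat.
#' @param qrs Numeric vector of QRS durations in seconds, same length.
#' @param rr Numeric vector of RR intervals in seconds, same length.
#' @param subject_id Character label for the subject.
#' @param beat_times Optional numeric vector of cumulative beat times in
#'   minutes; must be strictly increasing and the same length as the
#'   interval vectors.
#'
#' @return An object of class `interval_series`: a list with elements
#'   `subject_id`, `jt`, `qrs`, `rr` and (possibly `NULL`) `beat_times`.
#'
#' @examples
#' s <- interval_series(jt = c(0.30, 0.31, 0.32),
#'                      qrs = c(0.08, 0.09, 0.10),
#'                      rr = c(0.90, 1.00, 1.10))
#' n_beats(s)
#' @export
interval_series <- function(jt, qrs, rr, subject_id = "subject",
                            beat_times = NULL) {
  jt <- as.numeric(jt); qrs <- as.numeric(qrs); rr <- as.numeric(rr)
  n <- length(rr)
  if (length(jt) != n || length(qrs) != n)
    stop("jt, qrs and rr must have identical length (got ",
         length(jt), ", ", length(qrs), ", ", n, ")")
  if (n < 1) stop("interval series must contain at least one beat")
  for (nm in c("jt", "qrs", "rr")) {
    v <- get(nm)
    if (anyNA(v) || any(!is.finite(v)))
      stop("non-finite values in '", nm, "'")
    bad <- which(v <= 0)
    if (length(bad))
      stop("non-positive ", nm, " value at beat ", bad[1],
           " (", v[bad[1]], "); intervals must be > 0 seconds")
  }
  if (!is.null(beat_times)) {
    beat_times <- as.numeric(beat_times)
    if (length(beat_times) != n)
      stop("beat_times must have the same length as the interval vectors")
    if (any(diff(beat_times) <= 0))
      stop("beat_times must be strictly increasing")
  }
  structure(list(subject_id = as.character(subject_id)[1],
                 jt = jt, qrs = qrs, rr = rr, beat_times = beat_times),
            class = "interval_series")
}

#' Number of beats in an interval series
#' @param series An `interval_series` object.
#' @return Integer beat count.
#' @export
n_beats <- function(series) {
  stopifnot(inherits(series, "interval_series"))
  length(series$rr)
}

#' @export
print.interval_series <- function(x, ...) {
  cat("<interval_series> subject:", x$subject_id,
      "|", n_beats(x), "beats\n")
  cat(sprintf("  RR  mean %.3f s (sd %.4f)\n", mean(x$rr), stats::sd(x$rr)))
  cat(sprintf("  JT  mean %.3f s (sd %.4f)\n", mean(x$jt), stats::sd(x$jt)))
  cat(sprintf("  QRS mean %.3f s (sd %.4f)\n", mean(x$qrs), stats::sd(x$qrs)))
  invisible(x)
}

#' Read beat-wise intervals from a CSV file
#'
#' Expects a header row with columns `rr`, `jt`, `qrs` (case-insensitive),
#' one row per beat. Optional columns: `subject_id` (first value used) and
#' `time` (cumulative minutes). Values may be given in milliseconds with
#' `units = "ms"`, in which case they are converted to seconds.
#'
#' @param path Path to the CSV file.
#' @param units `"s"` (default) or `"ms"`.
#' @param subject_id Label to use when the file carries no `subject_id`
#'   column; defaults to the file name without extension.
#' @return An [interval_series()] object.
#' @export
read_intervals <- function(path, units = c("s", "ms"), subject_id = NULL) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  for (col in c("rr", "jt", "qrs"))
    if (!col %in% names(df))
      stop("missing required column '", col, "' in ", path)
  scale <- if (units == "ms") 1e-3 else 1
  id <- if ("subject_id" %in% names(df)) as.character(df$subject_id[1])
        else if (!is.null(subject_id)) subject_id
        else sub("\\.[^.]*$", "", basename(path))
  bt <- if ("time" %in% names(df)) df$time else NULL
  for (col in c("rr", "jt", "qrs")) {
    v <- df[[col]]
    if (anyNA(v) || any(!is.finite(v)) || any(v <= 0)) {
      bad <- which(is.na(v) | !is.finite(v) | v <= 0)[1]
      stop("invalid ", col, " value at row ", bad, " of ", path)
    }
  }
  interval_series(jt = df$jt * scale, qrs = df$qrs * scale,
                  rr = df$rr * scale, subject_id = id, beat_times = bt)
}

#' Write an interval series to CSV
#'
#' Inverse of [read_intervals()]: columns `subject_id`, `rr`, `jt`, `qrs`
#' (seconds) and, when present, `time` (minutes).
#'
#' @param series An `interval_series` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(series, path) {
  stopifnot(inherits(series, "interval_series"))
  df <- data.frame(subject_id = series$subject_id,
                   rr = series$rr, jt = series$jt, qrs = series$qrs)
  if (!is.null(series$beat_times)) df$time <- series$beat_times
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
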