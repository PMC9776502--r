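# shared fixtures and independent oracles

# the worked 3-beat example used across the matrix tests
tiny_series <- function() {
  interval_series(jt = c(0.30, 0.31, 0.32),
                  qrs = c(0.08, 0.09, 0.10),
                  rr = c(0.90, 1.00, 1.10),
                  subject_id = "tiny")
}

constant_series <- function(n = 30, jt = 0.30, qrs = 0.09, rr = 0.90) {
  interval_series(jt = rep(jt, n), qrs = rep(qrs, n), rr = rep(rr, n),
                  subject_id = "constant")
}

random_series <- function(n, seed) {
  set.seed(seed)
  interval_series(jt = runif(n, 0.25, 0.40),
                  qrs = runif(n, 0.07, 0.12),
                  rr = runif(n, 0.6, 1.2),
                  subject_id = paste0("rand", seed))
}

# brute-force Frobenius norm: explicit accumulation loop, no vectorization
frobenius_oracle <- function(m) {
  acc <- 0
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m)))
      acc <- acc + m[i, j]^2
  sqrt(acc)
}

# brute-force centered moving average with symmetric shrinking windows
moving_average_oracle <- function(x, r) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ri <- min(r, i - 1, n - i)
    out[i] <- mean(x[(i - ri):(i + ri)])
  }
  out
}

# per-beat loop oracle for the relationship sequence
relationship_oracle <- function(series, delta, order, vo, mapping) {
  N <- n_beats(series)
  sapply(seq.int(delta + 1, N - delta), function(n)
    map_to_scalar(build_matrix(series, n, delta, order, vo), mapping))
}

# reference per-subject variance columns of the shipped baseline
reference_healthy <- c(0.0012, 0.0030, 0.0023, 0.0014,
                       0.0040, 0.0025, 0.0031, 0.0018)
reference_unhealthy <- c(0.0006424, 0.0003502, 0.0082, 0.0015,
                         0.0064, 0.0030, 0.0014)
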