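test_that("indicator reproduces the reference worked examples", {
  iv <- reference_baseline()
  expect_equal(round(indicator(0.0018, iv)$ind, 2), 0.07)
  expect_equal(round(indicator(0.0040, iv)$ind, 2), 0.54)
  expect_equal(indicator(0.0018, iv)$condition, 3L)
})

test_that("indicator boundary identities, monotonicity and affine invariance", {
  mk_iv <- function(left, right) {
    # narrow synthetic fits with the requested boundaries
    h <- fit_cohort(rep(left, 4), "healthy")
    uh <- fit_cohort(rep(right, 4), "unhealthy")
    variation_interval(h, uh)
  }
  set.seed(7)
  for (i in 1:200) {
    left <- runif(1, 0, 5)
    right <- left + runif(1, 0.01, 5)
    iv <- mk_iv(left, right)
    expect_equal(indicator(left, iv)$ind, 0)
    expect_equal(indicator(right, iv)$ind, 1)
    expect_equal(indicator(left, iv)$condition, 1L)
    expect_equal(indicator(right, iv)$condition, 2L)
    # continuity just inside the boundaries
    eps <- (right - left) * 1e-9
    expect_lt(indicator(left + eps, iv)$ind, 1e-6)
    expect_gt(indicator(right - eps, iv)$ind, 1 - 1e-6)
    # non-decreasing in C
    cs <- sort(runif(8, left - 1, right + 1))
    inds <- sapply(cs, function(C) indicator(C, iv)$ind)
    expect_true(all(diff(inds) >= 0))
    expect_true(all(inds >= 0 & inds <= 1))
    # invariance under common affine rescaling
    a <- runif(1, 0.1, 3); b <- runif(1, 0, 2)
    C <- runif(1, left, right)
    iv2 <- mk_iv(a * left + b, a * right + b)
    expect_equal(indicator(a * C + b, iv2)$ind, indicator(C, iv)$ind,
                 tolerance = 1e-9)
  }
  # conditions map to the IND identities
  iv <- mk_iv(1, 2)
  expect_equal(indicator(0.5, iv), list(ind = 0, condition = 1L))
  expect_equal(indicator(9.0, iv), list(ind = 1, condition = 2L))
  r3 <- indicator(1.5, iv)
  expect_equal(r3$condition, 3L)
  expect_true(r3$ind > 0 && r3$ind < 1)
})

test_that("the transposed compatibility formula differs from the default", {
  iv <- reference_baseline()
  # under the transposed anchors the first worked example lands near 0.53
  expect_equal(round(indicator(0.0018, iv, formula = "transposed")$ind, 2),
               0.53, tolerance = 0.02)
  expect_error(
    indicator(0.002,
              variation_interval(fit_cohort(rep(0.001, 4), "healthy"),
                                 fit_cohort(rep(0.004, 4), "unhealthy")),
              formula = "transposed"),
    "anchors")
})

test_that("semi-gauge colors follow the thresholds and the worked examples", {
  iv <- reference_baseline()
  expect_identical(classify(0.0018, iv)$color, "green")
  expect_identical(classify(0.0040, iv)$color, "yellow")
  expect_identical(classify(1, iv)$color, "red")      # far right -> IND = 1
  expect_equal(classify(1, iv)$ind, 1)
  expect_identical(classify(0, iv)$color, "green")    # far left -> IND = 0

  # custom thresholds
  expect_identical(classify(0.0040, iv, green_max = 0.6)$color, "green")
  expect_identical(classify(0.0040, iv, green_max = 0.1,
                            red_min = 0.5)$color, "red")
  expect_error(classify(0.0018, iv, green_max = 0.5, red_min = 0.4),
               "thresholds")
  # classification refuses a degenerate interval
  suppressWarnings(
    bad <- variation_interval(fit_cohort(rep(0.004, 4), "healthy"),
                              fit_cohort(rep(0.001, 4), "unhealthy")))
  expect_error(classify(0.002, bad), "degenerate")
})

test_that("gauge reports carry IND as the needle and survive serialization", {
  iv <- reference_baseline()
  set.seed(17)
  path <- withr::local_tempfile(fileext = ".json")
  for (i in 1:100) {
    C <- runif(1, 0, 0.01)
    res <- classify(C, iv)
    rep <- gauge_report(res, path)
    expect_equal(rep$needle_fraction, res$ind)
    expect_identical(rep$color, res$color)
    back <- read_gauge_report(path)
    expect_equal(back$needle_fraction, rep$needle_fraction, tolerance = 1e-12)
    expect_identical(back$color, rep$color)
    expect_equal(back$condition, rep$condition)
    expect_equal(back$interval$left, rep$interval$left, tolerance = 1e-12)
  }
})
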