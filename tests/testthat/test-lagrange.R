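test_that("symbolic layouts match the canonical second- and third-order forms", {
  g2 <- symbolic_structure(2)
  expect_identical(g2[[1, 1]]$kind, "zeroth")
  expect_identical(g2[[1, 1]]$variables, "x")
  # element (1,2) is the forward difference x - y
  expect_identical(g2[[1, 2]]$variables, c("x", "y"))
  expect_identical(g2[[1, 2]]$offsets, c(1L, 1L))
  expect_identical(g2[[2, 1]]$offsets, c(-1L, -1L))

  g3 <- symbolic_structure(3)
  diag_vars <- sapply(1:3, function(i) g3[[i, i]]$variables)
  expect_identical(diag_vars, c("x", "y", "z"))
  # (2,1): backward (y - x); (1,3): forward (z - x); (3,2): backward (z - y)
  expect_identical(g3[[2, 1]]$variables, c("y", "x"))
  expect_identical(g3[[2, 1]]$offsets, c(-1L, -1L))
  expect_identical(g3[[1, 3]]$variables, c("z", "x"))
  expect_identical(g3[[1, 3]]$offsets, c(1L, 1L))
  expect_identical(g3[[3, 2]]$variables, c("z", "y"))
  expect_identical(g3[[3, 2]]$offsets, c(-1L, -1L))

  expect_error(symbolic_structure(4), "order")
})

test_that("five perfection conditions hold for both orders and fail on tampering", {
  for (k in c(2, 3)) {
    v <- validate_perfect_structure(symbolic_structure(k))
    expect_true(v$distinct_elements)
    expect_true(v$diagonal_zeroth_order)
    expect_true(v$offdiagonal_first_order)
    expect_true(v$time_balanced)
    expect_true(v$variable_balanced)
    expect_true(v$perfect)
  }
  # duplicating an off-diagonal element breaks distinctness only
  g <- symbolic_structure(3)
  g[[1, 2]] <- g[[2, 1]]
  v <- validate_perfect_structure(g)
  expect_false(v$distinct_elements)
  expect_false(v$perfect)
  # and moving an offset breaks the time balance
  g <- symbolic_structure(2)
  g[[2, 1]]$offsets <- c(1L, 1L)
  v <- validate_perfect_structure(g)
  expect_false(v$time_balanced)
  expect_error(validate_perfect_structure(matrix(list(1, 2, 3, 4), 2)),
               "malformed")
})

test_that("build_matrix substitutes interval values per the symbolic layout", {
  s <- tiny_series()
  m <- build_matrix(s, n = 2, delta = 1, order = 3)
  expect_equal(unclass(m)[, ],
               matrix(c(0.31, -0.22, 0.78,
                        -0.22, 0.09, 1.00,
                        0.60, 0.82, 1.00), 3, byrow = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
  m2 <- build_matrix(s, n = 2, delta = 1, order = 2,
                     variable_order = c("jt", "qrs"))
  expect_equal(unclass(m2)[, ],
               matrix(c(0.31, 0.22, 0.22, 0.09), 2, byrow = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)

  # constant input: diagonal holds the constants, differences vanish
  cs <- constant_series(5, jt = 0.3, qrs = 0.3, rr = 0.3)
  mc <- build_matrix(cs, 3, 1)
  expect_equal(diag(unclass(mc)), rep(0.3, 3))
  expect_equal(unclass(mc)[upper.tri(mc) | lower.tri(mc)], rep(0, 6))

  expect_error(build_matrix(s, n = 1, delta = 1), "window")
  expect_error(build_matrix(s, n = 3, delta = 1), "window")
  expect_error(build_matrix(s, n = 2, delta = 0), "positive")
  expect_error(build_matrix(s, n = 2, delta = 1,
                            variable_order = c("jt", "jt", "rr")),
               "variable_order")
})

test_that("diagonal multiset is preserved under variable_order permutation", {
  s <- random_series(9, seed = 4)
  perms <- list(c("jt", "qrs", "rr"), c("rr", "jt", "qrs"),
                c("qrs", "rr", "jt"), c("jt", "rr", "qrs"))
  diags <- lapply(perms, function(vo)
    sort(diag(unclass(build_matrix(s, 5, 2, 3, vo)))))
  for (d in diags[-1]) expect_equal(d, diags[[1]])
  # but the matrices themselves differ
  expect_false(isTRUE(all.equal(
    unclass(build_matrix(s, 5, 2, 3, perms[[1]]))[, ],
    unclass(build_matrix(s, 5, 2, 3, perms[[2]]))[, ])))
})

test_that("scalar mappings behave as defined", {
  s <- tiny_series()
  m <- build_matrix(s, 2, 1)
  expect_equal(map_to_scalar(m), frobenius_oracle(unclass(m)),
               tolerance = 1e-12)
  expect_equal(map_to_scalar(m), 1.960051, tolerance = 1e-6)
  z <- matrix(0, 3, 3)
  for (mp in c("frobenius_norm", "spectral_norm", "max_abs_eigenvalue"))
    expect_equal(map_to_scalar(z, mp), 0)
  # constant diagonal c: Frobenius = c * sqrt(order)
  cs <- constant_series(5, 0.4, 0.4, 0.4)
  expect_equal(map_to_scalar(build_matrix(cs, 2, 1)), 0.4 * sqrt(3),
               tolerance = 1e-12)
  # discriminant only defined for order 2
  expect_error(map_to_scalar(m, "discriminant"), "order-2")
  m2 <- matrix(c(1, 2, 3, 4), 2)
  expect_equal(map_to_scalar(m2, "discriminant"),
               (1 + 4)^2 - 4 * (1 * 4 - 3 * 2))
  # dominant eigenvalue modulus via complex spectrum
  rot <- matrix(c(0, -2, 2, 0), 2)
  expect_equal(map_to_scalar(rot, "max_abs_eigenvalue"), 2)
})

test_that("relationship_series matches the per-beat loop oracle", {
  for (seed in 1:5) {
    s <- random_series(20, seed)
    for (delta in c(1, 3)) {
      for (spec in list(list(2, c("jt", "qrs")), list(3, c("jt", "qrs", "rr")))) {
        rel <- relationship_series(s, delta, spec[[1]], spec[[2]])
        expect_length(rel$values, 20 - 2 * delta)
        expect_equal(rel$values,
                     relationship_oracle(s, delta, spec[[1]], spec[[2]],
                                         "frobenius_norm"),
                     tolerance = 1e-12)
        expect_equal(rel$center_indices, seq.int(delta + 1, 20 - delta))
      }
    }
  }
  # non-default mapping goes through the same per-matrix path
  s <- random_series(12, 9)
  rel <- relationship_series(s, 1, 3, mapping = "spectral_norm")
  expect_equal(rel$values,
               relationship_oracle(s, 1, 3, c("jt", "qrs", "rr"),
                                   "spectral_norm"),
               tolerance = 1e-12)
})

test_that("relationship sequence is local and constant-degenerate", {
  # constant series: every value is c * sqrt(3), zero variance
  cs <- constant_series(10, 0.5, 0.5, 0.5)
  rel <- relationship_series(cs, 1)
  expect_length(rel$values, 8)
  expect_equal(rel$values, rep(0.5 * sqrt(3), 8), tolerance = 1e-12)
  expect_equal(var(rel$values), 0)

  # locality: appending beats beyond n + delta leaves earlier values alone
  s <- random_series(30, seed = 6)
  long <- relationship_series(s, 2)$values
  short <- relationship_series(
    interval_series(s$jt[1:20], s$qrs[1:20], s$rr[1:20]), 2)$values
  expect_equal(long[seq_along(short)], short, tolerance = 1e-15)

  expect_error(relationship_series(constant_series(4), delta = 2), "short")
})
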