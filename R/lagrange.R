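#' Symbolic layout of a perfect matrix of Lagrange differences
#'
#' A perfect matrix of Lagrange differences holds zeroth-order differences
#' (raw series values) on its main diagonal and first-order differences
#' (differences between two series taken at a common time offset) on every
#' off-diagonal position, subject to five structural conditions: all
#' elements distinct, zeroth-order on the diagonal, first-order off the
#' diagonal, total time lag zero, and balanced use of the variable symbols.
#' This function returns the canonical symbolic layout for the second-order
#' (variables x, y) or third-order (variables x, y, z) matrix.
#'
#' Each element is a list with fields `kind` (`"zeroth"` or
#' `"difference"`), `variables` (one symbol, or the ordered pair
#' `c(a, b)` standing for `a - b`) and `offsets` (time offsets of the
#' operands in units of the lag delta: -1, 0 or +1).
#'
#' The second-order layout places `x[n]` and `y[n]` on the diagonal, the
#' forward difference `x[n+d] - y[n+d]` above it and the backward
#' difference `x[n-d] - y[n-d]` below it. The third-order layout keeps
#' `x[n]`, `y[n]`, `z[n]` on the diagonal, forward differences
#' `y - x`, `z - x`, `z - y` above it and the matching backward
#' differences below it.
#'
#' @param order Matrix order, 2 or 3.
#' @return A `lagrange_structure`: an `order` x `order` matrix of element
#'   lists with attribute `order`.
#' @seealso [validate_perfect_structure()], [build_matrix()]
#' @examples
#' symbolic_structure(3)
#' @export
symbolic_structure <- function(order) {
  if (!(length(order) == 1 && order %in% c(2, 3)))
    stop("unsupported matrix order: must be 2 or 3")
  zero <- function(v) list(kind = "zeroth", variables = v, offsets = 0L)
  diff_ <- function(a, b, off)
    list(kind = "difference", variables = c(a, b),
         offsets = c(off, off))
  if (order == 2) {
    g <- matrix(list(), 2, 2)
    g[[1, 1]] <- zero("x")
    g[[1, 2]] <- diff_("x", "y", +1L)
    g[[2, 1]] <- diff_("x", "y", -1L)
    g[[2, 2]] <- zero("y")
  } else {
    g <- matrix(list(), 3, 3)
    g[[1, 1]] <- zero("x")
    g[[1, 2]] <- diff_("y", "x", +1L)
    g[[1, 3]] <- diff_("z", "x", +1L)
    g[[2, 1]] <- diff_("y", "x", -1L)
    g[[2, 2]] <- zero("y")
    g[[2, 3]] <- diff_("z", "y", +1L)
    g[[3, 1]] <- diff_("z", "x", -1L)
    g[[3, 2]] <- diff_("z", "y", -1L)
    g[[3, 3]] <- zero("z")
  }
  structure(g, order = as.integer(order), class = "lagrange_structure")
}

element_signature <- function(el) {
  paste(el$kind, paste(el$variables, collapse = "-"),
        paste(el$offsets, collapse = ","), sep = "|")
}

#' @export
print.lagrange_structure <- function(x, ...) {
  k <- attr(x, "order")
  fmt <- function(el) {
    off <- function(o) c("-d", "", "+d")[o + 2L]
    if (el$kind == "zeroth") paste0(el$variables, "[n]")
    else paste0(el$variables[1], "[n", off(el$offsets[1]), "] - ",
                el$variables[2], "[n", off(el$offsets[2]), "]")
  }
  m <- matrix(vapply(x, fmt, character(1)), k, k)
  cat("<lagrange_structure> order", k, "\n")
  print(m, quote = FALSE)
  invisible(x)
}

#' Validate the five perfection conditions of a symbolic layout
#'
#' Checks the five conditions a matrix of Lagrange differences must satisfy
#' to be called perfect:
#' \enumerate{
#'   \item all elements are pairwise distinct,
#'   \item zeroth-order differences sit on the main diagonal,
#'   \item first-order differences occupy every off-diagonal position,
#'   \item the sum of time offsets over all difference elements is zero
#'     (time balance),
#'   \item every variable symbol appears equally often across the
#'     difference elements (lexicographic balance).
#' }
#'
#' @param grid A `lagrange_structure` as returned by
#'   [symbolic_structure()], or a plain square list-matrix of elements in
#'   the same format.
#' @return A list of class `structure_validation` with the five named
#'   logical checks (`distinct_elements`, `diagonal_zeroth_order`,
#'   `offdiagonal_first_order`, `time_balanced`, `variable_balanced`) and
#'   `perfect`, true iff all five hold.
#' @examples
#' validate_perfect_structure(symbolic_structure(2))$perfect
#' @export
validate_perfect_structure <- function(grid) {
  if (!is.matrix(grid) || nrow(grid) != ncol(grid))
    stop("grid must be a square matrix of symbolic elements")
  k <- nrow(grid)
  if (!k %in% c(2, 3)) stop("grid must have order 2 or 3")
  els <- as.list(grid)
  ok <- vapply(els, function(el) {
    is.list(el) && all(c("kind", "variables", "offsets") %in% names(el))
  }, logical(1))
  if (!all(ok)) stop("malformed grid: each element needs kind/variables/offsets")

  sigs <- vapply(els, element_signature, character(1))
  diag_idx <- (seq_len(k) - 1) * k + seq_len(k)
  kinds <- vapply(els, function(el) el$kind, character(1))
  diffs <- els[kinds == "difference"]

  checks <- list(
    distinct_elements = !anyDuplicated(sigs),
    diagonal_zeroth_order = all(kinds[diag_idx] == "zeroth"),
    offdiagonal_first_order = all(kinds[-diag_idx] == "difference"),
    time_balanced =
      sum(unlist(lapply(diffs, `[[`, "offsets"))) == 0,
    variable_balanced = {
      counts <- table(unlist(lapply(diffs, `[[`, "variables")))
      length(counts) == 0 || length(unique(as.integer(counts))) == 1
    }
  )
  checks$perfect <- all(unlist(checks))
  structure(checks, class = "structure_validation")
}

#' @export
print.structure_validation <- function(x, ...) {
  for (nm in setdiff(names(x), "perfect"))
    cat(sprintf("  %-24s %s\n", nm, if (x[[nm]]) "ok" else "FAIL"))
  cat("  perfect:", x$perfect, "\n")
  invisible(x)
}

#' Build a numeric perfect matrix of Lagrange differences at one beat
#'
#' Substitutes the interval values of one subject into the symbolic layout
#' at center beat `n` with lag `delta`. The variables x, y, z of the
#' layout are bound to the interval columns named in `variable_order`;
#' the study default binds x = JT, y = QRS, z = RR. For `order = 2` only
#' the first two entries of `variable_order` are used.
#'
#' @param series An [interval_series()] object.
#' @param n Center beat index, 1-based; must satisfy
#'   `delta + 1 <= n <= n_beats(series) - delta` so both the backward and
#'   the forward neighbor exist.
#' @param delta Time lag in beats (positive integer). Default 1.
#' @param order 2 or 3 (default 3).
#' @param variable_order Character permutation of `c("jt","qrs","rr")`.
#' @return A `lagrange_matrix`: a numeric `order` x `order` matrix with
#'   attributes `order`, `center_index`, `lag` and `variable_order`.
#' @examples
#' s <- interval_series(jt = c(0.30, 0.31, 0.32),
#'                      qrs = c(0.08, 0.09, 0.10),
#'                      rr = c(0.90, 1.00, 1.10))
#' build_matrix(s, n = 2, delta = 1)
#' @export
build_matrix <- function(series, n, delta = 1, order = 3,
                         variable_order = c("jt", "qrs", "rr")) {
  stopifnot(inherits(series, "interval_series"))
  delta <- as.integer(delta)
  if (length(delta) != 1 || is.na(delta) || delta < 1)
    stop("delta must be a positive integer (beats)")
  vo <- check_variable_order(variable_order, order)
  N <- n_beats(series)
  if (n < delta + 1 || n > N - delta)
    stop("center index n = ", n, " outside the valid window [",
         delta + 1, ", ", N - delta, "] for delta = ", delta)
  g <- symbolic_structure(order)
  cols <- list(x = series[[vo[1]]], y = series[[vo[2]]])
  if (order == 3) cols$z <- series[[vo[3]]]
  val <- function(sym, off) cols[[sym]][n + off * delta]
  m <- matrix(vapply(as.list(g), function(el) {
    if (el$kind == "zeroth") val(el$variables, el$offsets)
    else val(el$variables[1], el$offsets[1]) -
         val(el$variables[2], el$offsets[2])
  }, numeric(1)), order, order)
  structure(m, order = as.integer(order), center_index = as.integer(n),
            lag = delta, variable_order = vo[seq_len(min(order, 3))],
            class = c("lagrange_matrix", "matrix", "array"))
}

check_variable_order <- function(variable_order, order = 2) {
  vo <- tolower(as.character(variable_order))
  if (!all(vo %in% c("jt", "qrs", "rr")) || anyDuplicated(vo) ||
      length(vo) < min(order, 3))
    stop("variable_order must be ", min(order, 3),
         " distinct names from jt/qrs/rr, got: ",
         paste(variable_order, collapse = ", "))
  vo
}

#' Map a matrix of Lagrange differences to a scalar
#'
#' The matrix-to-scalar mapping turns the matrix trajectory into a scalar
#' relationship sequence. The default is the Frobenius norm; the spectral
#' norm, the modulus of the dominant eigenvalue and (for order 2 only) the
#' discriminant of the characteristic polynomial are available
#' alternatives.
#'
#' @param m A `lagrange_matrix` or plain square numeric matrix.
#' @param mapping One of `"frobenius_norm"`, `"spectral_norm"`,
#'   `"max_abs_eigenvalue"`, `"discriminant"`.
#' @return A single numeric value; non-negative for the norm mappings.
#' @export
map_to_scalar <- function(m, mapping = c("frobenius_norm", "spectral_norm",
                                         "max_abs_eigenvalue",
                                         "discriminant")) {
  mapping <- match.arg(mapping)
  m <- unclass(m)
  attributes(m) <- attributes(m)["dim"]
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("m must be a square numeric matrix")
  switch(mapping,
    frobenius_norm = sqrt(sum(m^2)),
    spectral_norm = max(svd(m, nu = 0, nv = 0)$d),
    max_abs_eigenvalue = max(Mod(eigen(m, only.values = TRUE)$values)),
    discriminant = {
      if (nrow(m) != 2)
        stop("discriminant mapping is defined for order-2 matrices only")
      # discriminant of the characteristic polynomial: tr^2 - 4 det
      (m[1, 1] + m[2, 2])^2 - 4 * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])
    })
}

#' Scalar relationship sequence from a matrix trajectory
#'
#' Slides the perfect-matrix construction along the beat series and maps
#' every matrix to a scalar: value k of the result corresponds to center
#' beat `n = delta + k`, and the sequence has length `N - 2 * delta`
#' because the first and last `delta` beats lack a neighbor.
#'
#' @inheritParams build_matrix
#' @inheritParams map_to_scalar
#' @return A `relationship_series`: list with `values`, `center_indices`,
#'   `smoothing` (radii applied so far, `c(0, 0)` here) and the provenance
#'   fields `delta`, `order`, `variable_order`, `mapping`, `subject_id`.
#' @examples
#' s <- interval_series(jt = rep(0.3, 10), qrs = rep(0.09, 10),
#'                      rr = rep(0.9, 10))
#' relationship_series(s, delta = 1)$values
#' @export
relationship_series <- function(series, delta = 1, order = 3,
                                variable_order = c("jt", "qrs", "rr"),
                                mapping = "frobenius_norm") {
  stopifnot(inherits(series, "interval_series"))
  delta <- as.integer(delta)
  if (delta < 1) stop("delta must be a positive integer")
  N <- n_beats(series)
  if (N < 2 * delta + 1)
    stop("series too short: need at least ", 2 * delta + 1,
         " beats for delta = ", delta, ", got ", N)
  vo <- check_variable_order(variable_order, order)
  centers <- seq.int(delta + 1, N - delta)
  g <- symbolic_structure(order)
  cols <- list(x = series[[vo[1]]], y = series[[vo[2]]])
  if (order == 3) cols$z <- series[[vo[3]]]
  # one column per symbolic element (column-major), one row per center beat
  entries <- vapply(as.list(g), function(el) {
    if (el$kind == "zeroth") cols[[el$variables]][centers]
    else cols[[el$variables[1]]][centers + el$offsets[1] * delta] -
         cols[[el$variables[2]]][centers + el$offsets[2] * delta]
  }, numeric(length(centers)))
  entries <- matrix(entries, nrow = length(centers))
  vals <- if (identical(mapping, "frobenius_norm")) {
    sqrt(rowSums(entries^2))
  } else {
    apply(entries, 1L, function(row)
      map_to_scalar(matrix(row, order, order), mapping))
  }
  structure(list(values = vals, center_indices = centers,
                 smoothing = c(r_internal = 0L, r_external = 0L),
                 delta = delta, order = as.integer(order),
                 variable_order = vo, mapping = mapping,
                 subject_id = series$subject_id),
            class = "relationship_series")
}

#' @export
print.relationship_series <- function(x, ...) {
  cat("<relationship_series>", x$subject_id, "| order", x$order,
      "| delta", x$delta, "|", length(x$values), "values\n")
  cat("  variables (x,y,z):", paste(x$variable_order, collapse = ", "),
      "| mapping:", x$mapping,
      "| smoothing radii:", paste(x$smoothing, collapse = "/"), "\n")
  invisible(x)
}
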