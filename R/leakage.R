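#' Unidirectional draining-vein leakage matrix
#'
#' Ascending venules drain deoxygenated blood from deep layers toward the
#' pial surface, so BOLD signal generated at depth leaks into more
#' superficial measurements. This constructor parameterizes that carry-over
#' with a single fraction `lambda` per depth step: with bins ordered from
#' pial (index 1) to white matter (index n), the measured signal obeys the
#' recursion `measured[i] = local[i] + lambda * measured[i + 1]`, i.e.
#' `L[i, j] = lambda^(j - i)` for `j >= i`. The matrix is triangular (zero
#' below the diagonal in this pial-first ordering) because drainage is
#' strictly unidirectional toward the surface.
#'
#' Published vascular-model coefficient tables can be supplied instead via
#' [as_leakage_matrix()].
#'
#' @param n number of depth bins.
#' @param lambda per-step carry fraction in `[0, 1)` (default 0.3).
#' @return An `n x n` matrix of class `leakage_matrix`.
#' @export
leakage_matrix <- function(n, lambda = 0.3) {
  stopifnot(n >= 1, lambda >= 0, lambda < 1)
  i <- row(diag(n)); j <- col(diag(n))
  L <- ifelse(j >= i, lambda^(j - i), 0)
  as_leakage_matrix(matrix(L, n, n))
}

#' Validate and tag a depth-leakage matrix
#'
#' Accepts any user-supplied square matrix over depth bins (pial-first
#' ordering) with positive diagonal, non-negative entries, and zeros below
#' the diagonal (no drainage away from the surface).
#'
#' @param mat square numeric matrix.
#' @return `mat` with class `leakage_matrix`.
#' @export
as_leakage_matrix <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (any(diag(mat) <= 0)) stop("leakage matrix diagonal must be positive")
  if (any(mat < 0)) stop("leakage matrix entries must be non-negative")
  if (any(mat[lower.tri(mat)] != 0))
    stop("leakage must be unidirectional toward the pial surface")
  structure(mat, class = c("leakage_matrix", "matrix"))
}

#' Read a leakage matrix from a delimited text file
#'
#' Reads a published depth-to-depth coefficient table (e.g. a transcribed
#' vascular-model matrix) from TSV/CSV, validating it as a leakage operator.
#'
#' @param path file path to a headerless numeric table.
#' @param sep field separator (default tab).
#' @return A `leakage_matrix`.
#' @export
read_leakage_matrix <- function(path, sep = "\t") {
  mat <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  dimnames(mat) <- NULL
  as_leakage_matrix(mat)
}

#' Apply the drainage forward model
#'
#' Maps local (neuronally generated) depth signal to measured signal,
#' `measured = L %*% local`, applied column-wise when `x` is a depth-by-time
#' matrix.
#'
#' @param x numeric vector over depth, or depth-by-time matrix.
#' @param L a [leakage_matrix()].
#' @return Drained signal, same shape as `x`.
#' @export
apply_leakage <- function(x, L) {
  n <- nrow(L)
  if (is.matrix(x)) {
    stopifnot(nrow(x) == n)
    unclass(L) %*% x
  } else {
    stopifnot(length(x) == n)
    drop(unclass(L) %*% x)
  }
}

#' Deconvolve the drainage effect from a depth profile
#'
#' Inverts the triangular leakage operator by back-substitution, recovering
#' the local depth profile from the measured one: solves `L x = profile`.
#'
#' @param profile numeric vector over depth (pial-first), or depth-by-time
#'   matrix.
#' @param L a [leakage_matrix()] of matching dimension.
#' @return Corrected profile on the same grid.
#' @export
deconvolve_profile <- function(profile, L) {
  if (any(abs(diag(L)) < .Machine$double.eps))
    stop("singular leakage matrix")
  if (is.matrix(profile)) {
    stopifnot(nrow(profile) == nrow(L))
    backsolve(unclass(L), profile)
  } else {
    stopifnot(length(profile) == nrow(L))
    drop(backsolve(unclass(L), profile))
  }
}
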