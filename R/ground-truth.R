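#' Ground-truth laminar response profiles for the synthetic generator
#'
#' Defines the known depth-dependent response amplitude (percent signal
#' change at peak) for each stimulus condition, on the normalized depth axis
#' `d` in `[0, 1]` with 0 = pial surface and 1 = white-matter boundary.
#'
#' Shapes emulate the qualitative laminar signatures of feedforward versus
#' contextual processing:
#' \itemize{
#'   \item `center` (stimulus-driven): amplitude increasing toward the pial
#'     surface — a linear draining-vein-like ramp `a * (1 - d)` — plus a
#'     small bump at middle depths (`c * N(d; 0.5, 0.1)`) where ascending
#'     thalamic projections terminate.
#'   \item `large` (contextual): positive peaks at superficial (`d = 0.25`)
#'     and deep (`d = 0.75`) depths where descending connections terminate,
#'     with a negative deflection at middle depths:
#'     `p1 * N(d; 0.25, sg) + p2 * N(d; 0.75, sg) - m * N(d; 0.5, sg)`.
#'   \item `medium`: a configurable mixture of the two
#'     (`mix * center + (1 - mix) * large`).
#' }
#' `N` denotes a unit-maximum Gaussian.
#'
#' @param condition one of `"center"`, `"medium"`, `"large"`.
#' @param params named list of shape parameters; defaults:
#'   `a = 1.5`, `c = 0.3` (center), `p1 = 1.0`, `p2 = 0.8`, `m = 1.2`,
#'   `sigma_g = 0.12` (large), `mix = 0.5` (medium).
#' @return An object of class `ground_truth_profile`: list with `condition`,
#'   `depth_fn` (vectorised function of normalized depth), and `params`.
#' @export
make_ground_truth <- function(condition,
                              params = list()) {
  condition <- match.arg(condition, c("center", "medium", "large"))
  p <- utils::modifyList(list(a = 1.5, c = 0.3, p1 = 1.0, p2 = 0.8,
                              m = 1.2, sigma_g = 0.12, mix = 0.5), params)
  nmax <- function(d, mu, s) exp(-(d - mu)^2 / (2 * s^2))
  center_fn <- function(d) p$a * (1 - d) + p$c * nmax(d, 0.5, 0.1)
  large_fn <- function(d) {
    p$p1 * nmax(d, 0.25, p$sigma_g) + p$p2 * nmax(d, 0.75, p$sigma_g) -
      p$m * nmax(d, 0.5, p$sigma_g)
  }
  fn <- switch(condition,
               center = center_fn,
               large = large_fn,
               medium = function(d) {
                 p$mix * center_fn(d) + (1 - p$mix) * large_fn(d)
               })
  structure(list(condition = condition, depth_fn = fn, params = p),
            class = "ground_truth_profile")
}

#' Evaluate a ground-truth profile on the standard 20-point grid
#'
#' Either directly on the continuous normalized-depth grid, or — when
#' `gm_depths` is given — through the same sample-then-interpolate path a
#' measured session takes: the profile is sampled at the session's
#' gray-matter depth positions and linearly re-gridded to `n_out` points.
#' The latter is the ground truth actually recoverable from a session with a
#' finite number of depth samples.
#'
#' @param truth a [make_ground_truth()] object.
#' @param gm_depths optional normalized depths of the session's gray-matter
#'   samples.
#' @param n_out output grid size (default 20).
#' @return Numeric vector of `n_out` amplitudes.
#' @export
ground_truth_on_grid <- function(truth, gm_depths = NULL, n_out = 20) {
  grid <- seq(0, 1, length.out = n_out)
  if (is.null(gm_depths)) return(truth$depth_fn(grid))
  stats::approx(gm_depths, truth$depth_fn(gm_depths), xout = grid,
                rule = 2)$y
}
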