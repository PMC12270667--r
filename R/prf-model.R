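#' Population receptive field parameters (divisive-normalization model)
#'
#' Bundles the location and divisive-normalization (DN) parameters of one
#' target population receptive field (pRF). The DN model expresses the
#' response of a cortical patch as the ratio of an activation pool (a narrow
#' Gaussian of width \code{sigma1}) and a normalization pool (a broader
#' Gaussian of width \code{sigma2}), each with its own amplitude and additive
#' baseline constant. This form produces size tuning and surround
#' suppression: responses grow with stimulus size up to an optimum and then
#' decline as the normalization pool is recruited.
#'
#' @param x,y pRF centre in visual space (degrees of visual angle, dva).
#' @param sigma1 activation-pool width (dva), must be positive.
#' @param sigma2 normalization-pool width (dva), must be `>= sigma1`.
#' @param amp_act activation amplitude (a.u.).
#' @param amp_norm normalization amplitude (a.u.).
#' @param b activation baseline constant (a.u.).
#' @param d normalization baseline constant (a.u.), must be positive.
#' @param r2 variance explained of the pRF model fit, in `[0, 1]`.
#'
#' @return An object of class `prf_params` (a list) with the fields above plus
#'   the derived `eccentricity = sqrt(x^2 + y^2)`.
#' @examples
#' prf <- prf_params(x = 2, y = 1, sigma1 = 0.7, sigma2 = 2.1)
#' prf$eccentricity
#' @export
prf_params <- function(x = 2, y = 1, sigma1 = 0.7, sigma2 = 2.1,
                       amp_act = 1, amp_norm = 0.05, b = 50, d = 500,
                       r2 = 0.75) {
  stopifnot(sigma1 > 0, sigma2 >= sigma1, d > 0, r2 >= 0, r2 <= 1)
  structure(list(x = x, y = y, sigma1 = sigma1, sigma2 = sigma2,
                 amp_act = amp_act, amp_norm = amp_norm, b = b, d = d,
                 r2 = r2, eccentricity = sqrt(x^2 + y^2)),
            class = "prf_params")
}

#' Screen geometry for stimulus rasters
#'
#' @param half_width,half_height half-extents of the visible screen (dva).
#' @param pixels_per_dva raster resolution (px/dva).
#' @return An object of class `screen_geometry`.
#' @export
screen_geometry <- function(half_width = 8, half_height = 4.5,
                            pixels_per_dva = 20) {
  stopifnot(half_width > 0, half_height > 0, pixels_per_dva > 0)
  structure(list(half_width = half_width, half_height = half_height,
                 pixels_per_dva = pixels_per_dva),
            class = "screen_geometry")
}

# Pixel-centre coordinate axes covering the screen.
screen_axes <- function(screen) {
  step <- 1 / screen$pixels_per_dva
  list(x = seq(-screen$half_width + step / 2, screen$half_width, by = step),
       y = seq(-screen$half_height + step / 2, screen$half_height, by = step))
}

# Unit-amplitude isotropic 2-D Gaussian rasterised on the screen grid
# (rows = y, cols = x).
gaussian_raster <- function(screen, x0, y0, sigma) {
  ax <- screen_axes(screen)
  gx <- exp(-(ax$x - x0)^2 / (2 * sigma^2))
  gy <- exp(-(ax$y - y0)^2 / (2 * sigma^2))
  outer(gy, gx)
}

# Binary disc mask of given radius centred on (x0, y0).
disc_mask <- function(screen, x0, y0, radius) {
  ax <- screen_axes(screen)
  dx2 <- outer(rep(1, length(ax$y)), (ax$x - x0)^2)
  dy2 <- outer((ax$y - y0)^2, rep(1, length(ax$x)))
  (dx2 + dy2 <= radius^2) * 1
}

#' Divisive-normalization response to a stimulus raster
#'
#' Computes the scalar DN-pRF response
#' \deqn{R = \frac{a_{act}\langle S, G_1\rangle + b}
#'            {a_{norm}\langle S, G_2\rangle + d} - \frac{b}{d}}
#' where \eqn{G_1, G_2} are unit-amplitude isotropic Gaussians at the pRF
#' centre with widths `sigma1`, `sigma2`, and the inner products are raster
#' sums over the screen. The subtraction of `b/d` anchors the response to an
#' empty stimulus at exactly zero.
#'
#' @param stim_mask numeric matrix (rows = y, cols = x) on the screen raster;
#'   typically binary.
#' @param prf a [prf_params()] object.
#' @param screen a [screen_geometry()] object matching `stim_mask`.
#' @return Scalar response (a.u.).
#' @export
dn_response <- function(stim_mask, prf, screen) {
  ax <- screen_axes(screen)
  stopifnot(is.matrix(stim_mask),
            nrow(stim_mask) == length(ax$y), ncol(stim_mask) == length(ax$x))
  if (prf$x - 3 * prf$sigma2 < -screen$half_width ||
      prf$x + 3 * prf$sigma2 > screen$half_width ||
      prf$y - 3 * prf$sigma2 < -screen$half_height ||
      prf$y + 3 * prf$sigma2 > screen$half_height)
    warning("truncated pRF support")
  g1 <- gaussian_raster(screen, prf$x, prf$y, prf$sigma1)
  g2 <- gaussian_raster(screen, prf$x, prf$y, prf$sigma2)
  num <- prf$amp_act * sum(stim_mask * g1) + prf$b
  den <- prf$amp_norm * sum(stim_mask * g2) + prf$d
  num / den - prf$b / prf$d
}

#' Size-tuning curve of a pRF
#'
#' Simulated response to centred discs of increasing radius, emulating the
#' classical size-tuning experiment: discs from 0 to 10 dva are passed
#' through the DN forward model.
#'
#' @param prf a [prf_params()] object.
#' @param screen a [screen_geometry()] object.
#' @param n_radii number of radii on the uniform grid over `[0, 10]` dva
#'   (default 101).
#' @return An object of class `size_tuning_curve`: list with `radii` and
#'   `responses`.
#' @export
size_tuning_curve <- function(prf, screen, n_radii = 101) {
  stopifnot(n_radii >= 2)
  radii <- seq(0, 10, length.out = n_radii)
  g1 <- gaussian_raster(screen, prf$x, prf$y, prf$sigma1)
  g2 <- gaussian_raster(screen, prf$x, prf$y, prf$sigma2)
  ax <- screen_axes(screen)
  r2grid <- outer((ax$y - prf$y)^2, rep(1, length(ax$x))) +
    outer(rep(1, length(ax$y)), (ax$x - prf$x)^2)
  ord <- order(r2grid)
  # cumulative raster sums over discs of growing radius: one sort instead of
  # n_radii full mask multiplications
  cs1 <- cumsum(g1[ord])
  cs2 <- cumsum(g2[ord])
  idx <- findInterval(radii^2, r2grid[ord])
  s1 <- ifelse(idx == 0, 0, cs1[pmax(idx, 1)])
  s2 <- ifelse(idx == 0, 0, cs2[pmax(idx, 1)])
  responses <- (prf$amp_act * s1 + prf$b) / (prf$amp_norm * s2 + prf$d) -
    prf$b / prf$d
  structure(list(radii = radii, responses = responses),
            class = "size_tuning_curve")
}

#' Optimal (maximum-response) stimulus size from a size-tuning curve
#'
#' @param curve a [size_tuning_curve()] object.
#' @return Radius (dva) at the global maximum; ties broken toward the
#'   smaller radius.
#' @export
optimal_center_size <- function(curve) {
  stopifnot(length(curve$radii) >= 1)
  if (diff(range(curve$responses)) == 0) stop("flat tuning curve")
  curve$radii[which.max(curve$responses)]
}

#' Largest non-occluded annulus radius for a pRF
#'
#' The outer radius of the large annulus is the smallest distance from the
#' pRF centre to any screen edge, so the full ring fits on screen.
#'
#' @inheritParams size_tuning_curve
#' @return Outer radius (dva) of the large annulus.
#' @export
largest_annulus_radius <- function(prf, screen) {
  if (abs(prf$x) >= screen$half_width || abs(prf$y) >= screen$half_height)
    stop("pRF centre lies outside the screen")
  min(screen$half_width - prf$x, screen$half_width + prf$x,
      screen$half_height - prf$y, screen$half_height + prf$y)
}

#' Medium annulus radius halfway between centre stimulus and large annulus
#'
#' @param center_outer outer radius of the centre stimulus (dva).
#' @param large_outer outer radius of the large annulus (dva).
#' @return List with `mid` radius and the 2-dva-wide ring bounds
#'   `inner = mid - 1`, `outer = mid + 1`. Warns when the ring spatially
#'   overlaps either neighbouring stimulus.
#' @export
medium_annulus_radius <- function(center_outer, large_outer) {
  stopifnot(large_outer > center_outer)
  mid <- (center_outer + large_outer) / 2
  inner <- mid - 1
  outer <- mid + 1
  if (inner < center_outer || outer > large_outer - 2)
    warning("medium annulus overlaps a neighbouring stimulus")
  list(mid = mid, inner = inner, outer = outer)
}

#' Stimulus specification
#'
#' @param kind one of `"center"`, `"medium"`, `"large"`.
#' @param inner_radius,outer_radius ring bounds (dva); `inner_radius = 0`
#'   for the centre stimulus. Annuli are 2 dva wide.
#' @param radial_cycles_per_deg,angular_cycles_per_deg checkerboard spatial
#'   frequencies, in cycles per degree of stimulus size.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(kind, inner_radius, outer_radius,
                          radial_cycles_per_deg = 2,
                          angular_cycles_per_deg = 1) {
  kind <- match.arg(kind, c("center", "medium", "large"))
  stopifnot(inner_radius >= 0, inner_radius < outer_radius)
  structure(list(kind = kind, inner_radius = inner_radius,
                 outer_radius = outer_radius,
                 radial_cycles_per_deg = radial_cycles_per_deg,
                 angular_cycles_per_deg = angular_cycles_per_deg),
            class = "stimulus_spec")
}

#' Render a radial checkerboard stimulus raster
#'
#' Produces the contrast raster of a flickering radial checkerboard: the sign
#' of the product of a radial square wave (`radial_cycles_per_deg *
#' outer_radius` cycles across the stimulus extent) and an angular square
#' wave (`angular_cycles_per_deg * outer_radius` cycles per full turn),
#' masked to the ring `[inner_radius, outer_radius]` around the pRF centre.
#' `phase = 1` gives the opposite flicker frame (contrast inverted).
#'
#' @param spec a [stimulus_spec()] object.
#' @param prf a [prf_params()] object (the stimulus is centred on the pRF).
#' @param screen a [screen_geometry()] object.
#' @param phase flicker phase, 0 or 1.
#' @return Matrix in `{-1, 0, 1}` on the screen raster.
#' @export
render_checkerboard <- function(spec, prf, screen, phase = 0) {
  stopifnot(phase %in% c(0, 1))
  ax <- screen_axes(screen)
  dx <- outer(rep(1, length(ax$y)), ax$x - prf$x)
  dy <- outer(ax$y - prf$y, rep(1, length(ax$x)))
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  n_rad <- spec$radial_cycles_per_deg * spec$outer_radius
  n_ang <- spec$angular_cycles_per_deg * spec$outer_radius
  rad_wave <- sign(sin(2 * pi * n_rad * r / spec$outer_radius))
  ang_wave <- sign(sin(n_ang * th))
  img <- rad_wave * ang_wave
  img[r < spec$inner_radius | r > spec$outer_radius] <- 0
  if (phase == 1) img <- -img
  img
}

#' FWHM band and zero crossings of a pRF's spatial response profile
#'
#' Evaluates the radial first-order response profile of the DN-pRF to a weak
#' point probe at distance `r` from the centre,
#' \eqn{p(r) \propto a_{act} d\, G_1(r) - b\, a_{norm} G_2(r)}, which is the
#' derivative of the DN response with respect to probe contrast at zero.
#' With no normalization amplitude the profile reduces to the activation
#' Gaussian. Returns the radii where the profile crosses half its maximum
#' (FWHM band) and, when the surround drives the profile negative, the radius
#' where it changes sign.
#'
#' @param prf a [prf_params()] object.
#' @param r_max evaluation extent (dva); default `5 * sigma2`.
#' @param n_grid grid points for bracketing (default 2001).
#' @return List with `fwhm` (`c(-w, w)` radii at half maximum, dva),
#'   `fwhm_width`, and `zero_crossings` (`c(-r0, r0)` or `NULL`).
#' @export
spatial_profile_markers <- function(prf, r_max = 5 * prf$sigma2,
                                    n_grid = 2001) {
  p <- function(r) {
    (prf$amp_act * prf$d * exp(-r^2 / (2 * prf$sigma1^2)) -
       prf$b * prf$amp_norm * exp(-r^2 / (2 * prf$sigma2^2))) / prf$d^2
  }
  r <- seq(0, r_max, length.out = n_grid)
  pr <- p(r)
  pmax_val <- pr[1]  # isotropic profile peaks at the centre
  half <- function(r) p(r) - pmax_val / 2
  i <- which(pr <= pmax_val / 2)[1]
  w <- stats::uniroot(half, c(r[i - 1], r[i]), tol = 1e-12)$root
  zc <- NULL
  flips <- which(diff(sign(pr)) != 0)
  if (length(flips) > 0) {
    j <- flips[1]
    r0 <- stats::uniroot(p, c(r[j], r[j + 1]), tol = 1e-12)$root
    zc <- c(-r0, r0)
  }
  list(fwhm = c(-w, w), fwhm_width = 2 * w, zero_crossings = zc)
}

#' Filter pRF candidate vertices by the selection criteria
#'
#' Keeps candidate pRFs inside the 1.5--3 dva eccentricity band, at least
#' 1 dva away from the vertical meridian, with variance explained strictly
#' above 0.55 and activation-pool size strictly above 0.50 dva.
#'
#' @param table data.frame with columns `eccentricity`, `merid_dist`, `r2`,
#'   `sigma1` (extra columns are carried through).
#' @return The surviving rows. Warns (does not error) when none survive.
#' @export
filter_prf_candidates <- function(table) {
  stopifnot(all(c("eccentricity", "merid_dist", "r2", "sigma1") %in%
                  names(table)))
  keep <- table$eccentricity >= 1.5 & table$eccentricity <= 3 &
    table$merid_dist >= 1 & table$r2 > 0.55 & table$sigma1 > 0.50
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no pRF candidates survive the selection filter")
  out
}

#' Read a tab-delimited pRF parameter table
#'
#' Expected columns: `id, x, y, sigma1, sigma2, amp_act, amp_norm, b, d, r2,
#' merid_dist` (header required). An `eccentricity` column is added when
#' absent.
#'
#' @param path file path.
#' @return data.frame of candidates.
#' @export
read_prf_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE)
  if (!"eccentricity" %in% names(tab))
    tab$eccentricity <- sqrt(tab$x^2 + tab$y^2)
  tab
}

#' Derive the participant-specific stimulus set from a pRF
#'
#' Runs the full design chain: size-tuning simulation for the centre
#' stimulus size, screen-edge geometry for the large annulus, and the
#' halfway rule for the medium annulus.
#'
#' @inheritParams size_tuning_curve
#' @return Named list of three [stimulus_spec()] objects (`center`, `medium`,
#'   `large`) plus the `size_tuning` curve used.
#' @export
design_stimulus_set <- function(prf, screen, n_radii = 101) {
  curve <- size_tuning_curve(prf, screen, n_radii)
  center_r <- optimal_center_size(curve)
  large_outer <- largest_annulus_radius(prf, screen)
  med <- medium_annulus_radius(center_r, large_outer)
  list(center = stimulus_spec("center", 0, center_r),
       medium = stimulus_spec("medium", med$inner, med$outer),
       large = stimulus_spec("large", large_outer - 2, large_outer),
       size_tuning = curve)
}
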