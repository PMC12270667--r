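test_that("dn_response anchors the null stimulus at zero and matches the
          analytic Gaussian integral", {
  screen <- default_screen()
  prf <- prf_no_norm()
  empty <- matrix(0, 180, 320)
  expect_identical(dn_response(empty, prf, screen), 0)

  # full-field stimulus, no normalization: raster sum of the activation
  # Gaussian vs its closed-form integral
  full <- matrix(1, 180, 320)
  expected <- prf$amp_act * 2 * pi * prf$sigma1^2 * 20^2
  expect_equal(dn_response(full, prf, screen), expected, tolerance = 1e-3)
})

test_that("disc responses follow the closed-form encircled Gaussian energy", {
  screen <- default_screen()
  prf <- prf_no_norm()
  for (r in c(0.7, 1.5, 3)) {
    mask <- lamline:::disc_mask(screen, prf$x, prf$y, r)
    expected <- prf$amp_act * (1 - exp(-r^2 / (2 * prf$sigma1^2))) *
      2 * pi * prf$sigma1^2 * 20^2
    expect_equal(dn_response(mask, prf, screen), expected, tolerance = 0.01)
  }
})

test_that("dn_response warns when the raster truncates the pRF support", {
  screen <- default_screen()
  prf <- prf_params(x = 7, y = 0, sigma1 = 0.7, sigma2 = 2.1)
  expect_warning(dn_response(matrix(0, 180, 320), prf, screen),
                 "truncated")
})

test_that("dn_response is invariant to joint translation of stimulus and
          pRF", {
  screen <- default_screen()
  r1 <- suppressWarnings(local({
    prf <- prf_params(x = 0, y = 0)
    dn_response(lamline:::disc_mask(screen, 0, 0, 1.5), prf, screen)
  }))
  r2 <- suppressWarnings(local({
    prf <- prf_params(x = 1, y = -0.5)
    dn_response(lamline:::disc_mask(screen, 1, -0.5, 1.5), prf, screen)
  }))
  expect_equal(r1, r2, tolerance = 1e-3)
})

test_that("size tuning is monotone without suppression and peaks where the
          brute-force oracle peaks with it", {
  screen <- default_screen()
  curve <- size_tuning_curve(prf_no_norm(), screen)
  expect_equal(curve$responses[1], 0)
  expect_true(all(diff(curve$responses) >= -1e-12))
  # without suppression the curve saturates rather than peaking inside
  expect_gte(curve$responses[101], 0.999 * max(curve$responses))

  # suppressive parameter set: interior peak, checked against a brute-force
  # disc-by-disc evaluation on a 1001-point radius grid
  prf <- prf_params()
  curve <- size_tuning_curve(prf, screen)
  peak <- optimal_center_size(curve)
  expect_true(peak > 0 && peak < 10)

  ax <- lamline:::screen_axes(screen)
  g1 <- lamline:::gaussian_raster(screen, prf$x, prf$y, prf$sigma1)
  g2 <- lamline:::gaussian_raster(screen, prf$x, prf$y, prf$sigma2)
  d2 <- outer((ax$y - prf$y)^2, rep(1, length(ax$x))) +
    outer(rep(1, length(ax$y)), (ax$x - prf$x)^2)
  radii_fine <- seq(0, 10, length.out = 1001)
  oracle <- vapply(radii_fine, function(r) {
    m <- d2 <= r^2
    (prf$amp_act * sum(g1[m]) + prf$b) /
      (prf$amp_norm * sum(g2[m]) + prf$d) - prf$b / prf$d
  }, 0)
  expect_lt(abs(peak - radii_fine[which.max(oracle)]),
            10 / 100 + 1e-9)   # within one grid step of the 101-point curve
})

test_that("optimal_center_size breaks ties toward the smaller radius and
          rejects flat curves", {
  curve <- structure(list(radii = 0:3, responses = c(0, 1, 3, 2)),
                     class = "size_tuning_curve")
  expect_equal(optimal_center_size(curve), 2)
  curve$responses <- c(0, 3, 3, 2)
  expect_equal(optimal_center_size(curve), 1)
  curve$responses <- rep(1, 4)
  expect_error(optimal_center_size(curve), "flat")
})

test_that("large-annulus radius is the smallest distance to a screen edge", {
  screen <- default_screen()
  expect_equal(largest_annulus_radius(prf_params(x = 2, y = 1), screen), 3.5)
  expect_equal(largest_annulus_radius(prf_params(x = 0, y = 0), screen), 4.5)
  # horizontal midline: the half height constrains
  expect_equal(largest_annulus_radius(prf_params(x = 1, y = 0), screen), 4.5)
  expect_error(largest_annulus_radius(prf_params(x = 9, y = 0), screen),
               "outside")
  # fits on screen along the constraining direction
  for (xy in list(c(2, 1), c(-3, 2), c(0.5, -3))) {
    prf <- prf_params(x = xy[1], y = xy[2])
    r <- largest_annulus_radius(prf, screen)
    expect_lte(r + abs(prf$x), screen$half_width + 1e-12)
    expect_lte(r + abs(prf$y), screen$half_height + 1e-12)
    expect_lte(r, min(screen$half_width, screen$half_height) +
                 prf$eccentricity)
  }
})

test_that("medium annulus sits halfway and warns on overlap", {
  m <- suppressWarnings(medium_annulus_radius(1, 5))
  expect_equal(m$mid, 3)
  expect_equal(c(m$inner, m$outer), c(2, 4))
  expect_warning(m2 <- medium_annulus_radius(1, 3), "overlap")
  expect_equal(m2$mid, 2)
  expect_equal(suppressWarnings(medium_annulus_radius(1.4, 6.0))$mid, 3.7)
})

test_that("checkerboard rendering masks, inverts and balances correctly", {
  screen <- default_screen()
  prf <- prf_params(x = 1, y = 0.5)
  spec <- stimulus_spec("large", inner_radius = 1.5, outer_radius = 3.5)
  img0 <- render_checkerboard(spec, prf, screen, phase = 0)
  img1 <- render_checkerboard(spec, prf, screen, phase = 1)
  ax <- lamline:::screen_axes(screen)
  r <- sqrt(outer((ax$y - prf$y)^2, rep(1, length(ax$x))) +
              outer(rep(1, length(ax$y)), (ax$x - prf$x)^2))
  expect_true(all(img0[r > spec$outer_radius] == 0))
  expect_true(all(img0[r < spec$inner_radius] == 0))
  ring <- r >= spec$inner_radius & r <= spec$outer_radius
  expect_identical(img1[ring], -img0[ring])
  # square-wave contrast balance over the ring
  expect_lt(abs(mean(img0[ring])), 0.02)
})

test_that("checkerboard stimulus area agrees across raster resolutions", {
  prf <- prf_params(x = 1, y = 0.5)
  spec <- stimulus_spec("large", inner_radius = 1.5, outer_radius = 3.5)
  area <- vapply(c(20, 32), function(ppd) {
    img <- render_checkerboard(spec, prf, default_screen(ppd))
    sum(img != 0) / ppd^2
  }, 0)
  expect_lt(abs(area[1] - area[2]) / area[2], 0.02)
})

test_that("spatial profile markers recover the Gaussian FWHM and the
          surround zero crossing", {
  prf <- prf_no_norm()
  mk <- spatial_profile_markers(prf)
  expect_equal(mk$fwhm_width, 2 * sqrt(2 * log(2)) * prf$sigma1,
               tolerance = 1e-6)
  expect_null(mk$zero_crossings)

  # suppressive set: zero crossing where amp_act*d*G1 = b*amp_norm*G2,
  # solvable in closed form for two Gaussians
  prf <- prf_params()
  mk <- spatial_profile_markers(prf)
  r0 <- sqrt(log(prf$amp_act * prf$d / (prf$b * prf$amp_norm)) /
               (1 / (2 * prf$sigma1^2) - 1 / (2 * prf$sigma2^2)))
  expect_equal(mk$zero_crossings, c(-r0, r0), tolerance = 1e-6)
})

test_that("pRF candidate filter applies all four selection rules with the
          stated strictness", {
  row <- function(ecc, md, r2, s1)
    data.frame(eccentricity = ecc, merid_dist = md, r2 = r2, sigma1 = s1)
  expect_equal(nrow(filter_prf_candidates(row(2, 1.5, 0.6, 0.7))), 1)
  # boundary r2 = 0.55 is excluded (strict inequality)
  expect_equal(nrow(suppressWarnings(
    filter_prf_candidates(row(2, 1.5, 0.55, 0.7)))), 0)
  tab <- rbind(row(2, 1.5, 0.6, 0.7),    # passes all
               row(1.2, 1.5, 0.6, 0.7),  # eccentricity too low
               row(2, 0.5, 0.6, 0.7),    # too close to the meridian
               row(2, 1.5, 0.6, 0.4))    # pRF too small
  out <- filter_prf_candidates(tab)
  expect_equal(nrow(out), 1)
  expect_equal(out$eccentricity, 2)
  expect_warning(filter_prf_candidates(row(9, 0, 0, 0)), "no pRF")
})

test_that("the full stimulus-design chain yields a consistent triplet", {
  screen <- default_screen()
  prf <- prf_params()
  set <- suppressWarnings(design_stimulus_set(prf, screen))
  expect_equal(set$center$inner_radius, 0)
  expect_equal(set$large$outer_radius - set$large$inner_radius, 2)
  expect_equal((set$medium$inner_radius + set$medium$outer_radius) / 2,
               (set$center$outer_radius + set$large$outer_radius) / 2)
})
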