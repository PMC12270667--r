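test_that("echo combination: sum-of-squares and T2*-weighted schemes", {
  # 3-4-5 triple, per sample
  e <- array(0, c(2, 4, 2))
  e[, , 1] <- 3; e[, , 2] <- 4
  out <- combine_echoes(e, c(0.006, 0.014), "sos")
  expect_equal(out$data, matrix(5, 2, 4))
  # single echo is the identity under sos
  e1 <- array(rnorm(8), c(2, 4, 1))
  expect_equal(combine_echoes(e1, 0.006, "sos")$data, e1[, , 1])

  # mono-exponential decay with known T2* = 28 ms: log-linear fit within 1%
  te <- c(6, 14, 22, 30, 38) / 1000
  t2_true <- 0.028
  base <- matrix(rep(c(800, 1000), 50), 2, 50)
  e <- array(0, c(2, 50, 5))
  for (k in 1:5) e[, , k] <- base * exp(-te[k] / t2_true)
  out <- combine_echoes(e, te, "t2star")
  expect_equal(out$t2star, rep(t2_true, 2), tolerance = 0.01)
  # weights sum to one: combining constant-in-time echoes preserves scale
  expect_equal(dim(out$data), c(2, 50))
})

test_that("Savitzky-Golay smoothing reproduces cubics and is idempotent on
          constants", {
  t <- seq_len(300)
  cubic <- 2 + 0.5 * t - 0.01 * t^2 + 1e-4 * t^3
  sm <- savgol_smooth(cubic)
  expect_equal(sm[16:285], cubic[16:285], tolerance = 1e-9)
  expect_equal(savgol_smooth(rep(3.2, 100)), rep(3.2, 100))
  expect_error(savgol_smooth(rnorm(20)), "window")
})

test_that("Savitzky-Golay noise gain matches the coefficient-norm formula", {
  half <- 15
  coefs <- signal::sgolay(p = 3, n = 31)[half + 1, ]
  gain <- sum(coefs^2)
  set.seed(3)
  x <- rnorm(1e4)
  v <- var(savgol_smooth(x)[half:(1e4 - half)])
  expect_lt(abs(v - gain) / gain, 0.1)
})

test_that("percent signal change is zero for constants and invariant to
          scale", {
  expect_equal(percent_signal_change(rep(7, 10)), rep(0, 10))
  s <- 100 * (1 + 0.01 * sin(1:50))
  expect_equal(percent_signal_change(s), percent_signal_change(3 * s))
  expect_error(percent_signal_change(rep(0, 10)), "zero median")
})

test_that("epoching yields 2 variants x 5 events per condition,
          baseline-corrects, and reproduces the noiseless expectation", {
  fix <- noiseless_profile("center")
  es <- fix$epochs
  expect_equal(sum(es$condition == "center"), 10)
  expect_equal(length(es$time), round(16 / 0.105))
  expect_equal(es$n_dropped, 0)

  # constant series epochs are all zero after baseline correction
  runs <- fix$runs
  const_runs <- lapply(runs, function(r) {
    r$data <- matrix(5, nrow(r$data), ncol(r$data)); r
  })
  esc <- epoch_and_average(const_runs, tr = 0.105)
  expect_true(all(abs(esc$means[["center"]]) < 1e-12))

  # noiseless mean response equals the baseline-corrected epoch average of
  # the HRF-convolved boxcar, regenerated from the generator's internals
  tr <- 0.105
  gm_row <- runs[[1]]$gm_bounds[1] + 2
  truth_d <- fix$session$truth[["center"]]$depth_fn(fix$session$gm_depths[3])
  expected <- 0
  n_epochs <- 0
  for (run in runs) {
    x <- truth_d * convolve_events(run$events$onset, run$events$duration,
                                   ncol(run$data), tr)
    x <- savgol_smooth(x)  # smoothing precedes epoching in the pipeline
    for (onset in run$events$onset) {
      i0 <- floor((onset - 2) / tr) + 1
      ep <- x[i0:(i0 + round(16 / tr) - 1)]
      expected <- expected + (ep - mean(ep[seq_len(round(2 / tr))]))
      n_epochs <- n_epochs + 1
    }
  }
  expected <- expected / n_epochs
  got <- es$means[["center"]][gm_row, ]
  expect_lt(max(abs(got - expected)), 1e-9)
})

test_that("epoch count conservation: truncated epochs are dropped with a
          warning", {
  run <- list(data = matrix(1 + 0.01 * sin(1:500), 3, 500, byrow = TRUE),
              events = data.frame(onset = c(10, 49), duration = 2,
                                  trial_type = "center"),
              variant = 1)
  run$data <- run$data + rnorm(1500, 0, 1e-3)
  es <- suppressWarnings(epoch_and_average(list(run), tr = 0.105))
  expect_equal(length(es$epochs) + es$n_dropped, 2)
  expect_equal(es$n_dropped, 1)
})

test_that("gray-matter re-gridding preserves constants, ramps and produces
          exactly 20 depths", {
  const <- matrix(4, 10, 3)
  out <- select_gm_and_regrid(const, c(2, 8))
  expect_equal(dim(out), c(20, 3))
  expect_true(all(out == 4))

  ramp <- matrix(rep(seq(0, 6), 2), 7, 2)
  out <- suppressWarnings(select_gm_and_regrid(ramp, c(1, 7)))
  expect_equal(out[, 1], seq(0, 6, length.out = 20))
  expect_equal(out[1, 1], 0)
  expect_equal(out[20, 1], 6)

  seven <- matrix(rnorm(7 * 5), 7, 5)
  expect_equal(nrow(select_gm_and_regrid(seven, c(1, 7))), 20)
  expect_error(select_gm_and_regrid(seven, c(3, 3)), "fewer than 2")
})

test_that("re-gridding commutes with averaging across time", {
  set.seed(9)
  m <- matrix(rnorm(7 * 40), 7, 40)
  a <- rowMeans(select_gm_and_regrid(m, c(1, 7)))
  b <- select_gm_and_regrid(rowMeans(m), c(1, 7))
  expect_equal(a, b)
})

test_that("line GLM quality: perfect regressor gives r2 = 1, noise near 0,
          and a well-formed synthetic session is included", {
  tr <- 0.105
  events <- data.frame(onset = c(20, 60, 100), duration = 2,
                       trial_type = "center")
  x <- convolve_events(events$onset, events$duration, 1500, tr)
  psc <- rbind(x, x, x, x, x, x, x)
  qc <- line_glm_quality(psc, events, tr, c(1, 7))
  expect_equal(unname(qc$r2), rep(1, 7), tolerance = 1e-9)

  set.seed(4)
  noise <- matrix(rnorm(7 * 1e4), 7, 1e4)
  ev2 <- data.frame(onset = seq(50, 900, by = 90), duration = 2,
                    trial_type = "center")
  qc2 <- line_glm_quality(noise, ev2, tr, c(1, 7))
  expect_true(all(qc2$r2 < 0.01))

  fix <- noiseless_profile("center")
  # add the other conditions so the inclusion contrast is defined
  cfg <- noiseless_config()
  pars <- lapply(1:2, function(v) build_paradigm(v, seed = 3))
  sess <- generate_session(pars, config = cfg, seed = 3)
  runs <- preprocess_session(sess)
  es <- epoch_and_average(runs, tr = tr)
  qc3 <- line_glm_quality(lapply(runs, `[[`, "data"),
                          lapply(runs, `[[`, "events"), tr,
                          runs[[1]]$gm_bounds, epoch_set = es)
  expect_true(qc3$included)
  expect_equal(qc3$shift, 0)
})

test_that("the preprocessing chain is linear: doubling the ground-truth
          amplitude doubles the evoked response", {
  f1 <- noiseless_profile("center", seed = 21)
  f2 <- noiseless_profile("center", seed = 21,
                          truth_params = list(a = 3.0, c = 0.6))
  expect_equal(2 * f1$m20, f2$m20, tolerance = 1e-9)
})
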