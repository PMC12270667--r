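test_that("ISI sampler respects its truncation bounds and target mean", {
  isi <- sample_isis(1e5, seed = 0)
  expect_true(all(isi >= 14 & isi <= 24))
  expect_lt(abs(mean(isi) - 18), 0.05)
  expect_identical(sample_isis(0), numeric(0))
  expect_error(sample_isis(10, isi_mean = 30), "infeasible")
})

test_that("paradigms carry 5 events per condition after the blank period,
          and variants differ", {
  p1 <- build_paradigm(variant = 1, seed = 42)
  p2 <- build_paradigm(variant = 2, seed = 42)
  expect_equal(as.integer(table(p1$events$trial_type)), rep(5L, 3))
  expect_gte(min(p1$events$onset), 72)
  expect_false(identical(p1$events$trial_type, p2$events$trial_type) &&
                 identical(p1$events$onset, p2$events$onset))
  # reproducible from (variant, seed)
  expect_identical(p1$events, build_paradigm(variant = 1, seed = 42)$events)
})

test_that("paradigm validity holds across many seeds", {
  for (seed in 1:50) {
    p <- build_paradigm(variant = 1 + seed %% 2, seed = seed)
    expect_equal(as.integer(table(p$events$trial_type)), rep(5L, 3))
    isi <- diff(p$events$onset) - p$events$duration[-1]
    expect_true(all(isi >= 14 - 1e-9 & isi <= 24 + 1e-9))
    expect_lte(max(p$events$onset) + 2 + 14, p$run_length)
  }
})

test_that("the canonical HRF peaks at 6 s, starts at zero, and its discrete
          sum matches a fine-grid quadrature", {
  tr <- 0.105
  h <- double_gamma_hrf(tr)
  t <- seq(0, 32, by = tr)
  expect_equal(h[1], 0)
  expect_lt(abs(t[which.max(h)] - 6), tr / 2 + 1e-12)
  expect_equal(max(h), 1)
  # quadrature oracle on a 1000x finer grid of the same closed form
  tf <- seq(0, 32, by = tr / 1000)
  hf <- lamline:::hrf_continuous(tf)
  hf <- hf / max(hf)
  expect_lt(abs(sum(h) * tr - sum(hf) * tr / 1000) / (sum(hf) * tr / 1000),
            0.01)
})

test_that("ground-truth laminar shapes have the intended geometry", {
  centre <- make_ground_truth("center")
  expect_gt(centre$depth_fn(0), centre$depth_fn(1))
  large <- make_ground_truth("large")
  expect_lt(large$depth_fn(0.5), 0)
  d <- seq(0, 1, length.out = 1001)
  v <- large$depth_fn(d)
  peaks <- which(diff(sign(diff(v))) == -2) + 1
  # the negative middle Gaussian pushes the maxima slightly outward
  expect_equal(d[peaks], c(0.25, 0.75), tolerance = 0.12)
  expect_error(make_ground_truth("oblique"))
})

test_that("drainage forward model matches the hand-unrolled 3-bin recursion
          and is linear", {
  L <- leakage_matrix(3, lambda = 0.3)
  expect_equal(unclass(L),
               matrix(c(1, 0, 0, 0.3, 1, 0, 0.09, 0.3, 1), 3, 3),
               ignore_attr = TRUE)
  # measured at pial = local + carry of everything deeper
  expect_equal(apply_leakage(c(1, 1, 1), L), c(1.39, 1.3, 1))
  expect_equal(apply_leakage(c(0, 0, 0), L), c(0, 0, 0))
  expect_identical(apply_leakage(c(1, 2, 3), leakage_matrix(3, 0)),
                   c(1, 2, 3))
  set.seed(1)
  x <- rnorm(3); y <- rnorm(3)
  expect_equal(apply_leakage(2 * x + 5 * y, L),
               2 * apply_leakage(x, L) + 5 * apply_leakage(y, L))
})

test_that("leakage matrices must be unidirectional toward the surface", {
  expect_error(as_leakage_matrix(matrix(c(1, 0.2, 0, 1), 2, 2)),
               "unidirectional")
  expect_error(as_leakage_matrix(diag(c(1, 0))), "diagonal")
})

test_that("the generator is deterministic, suppresses signal outside the
          ribbon, and reproduces the truth-by-HRF response noiselessly", {
  cfg <- noiseless_config(conditions = "center")
  par <- build_paradigm(1, seed = 5, conditions = "center")
  sess <- generate_session(list(par), config = cfg, seed = 5)
  sess2 <- generate_session(list(par), config = cfg, seed = 5)
  expect_identical(sess$runs[[1]]$ts$data, sess2$runs[[1]]$ts$data)

  ts <- sess$runs[[1]]$ts
  gm <- ts$gm_bounds[1]:ts$gm_bounds[2]
  out <- setdiff(seq_len(nrow(ts$data)), gm)
  expect_lt(mean(ts$data[out, ]), 0.1 * mean(ts$data[gm, ]))

  # noiseless round trip at a single depth: raw signal equals
  # baseline * (1 + truth(depth) * regressor / 100), regenerated here from
  # the generator's building blocks
  x <- convolve_events(par$events$onset, par$events$duration,
                       ncol(ts$data), cfg$tr)
  truth_d <- sess$truth[["center"]]$depth_fn(sess$gm_depths[3])
  expected <- cfg$baseline * (1 + truth_d * x / 100)
  expect_equal(ts$data[gm[3], ], expected, tolerance = 1e-12)
})

test_that("noisy generation with a fixed seed is reproducible and the
          multi-echo images decay with echo time", {
  cfg <- session_config(multi_echo = TRUE)
  par <- build_paradigm(1, seed = 8)
  s1 <- generate_session(list(par), config = cfg, seed = 8)
  s2 <- generate_session(list(par), config = cfg, seed = 8)
  expect_identical(s1$runs[[1]]$ts$echoes, s2$runs[[1]]$ts$echoes)
  e <- s1$runs[[1]]$ts$echoes
  gm_row <- s1$runs[[1]]$ts$gm_bounds[1]
  ratio <- mean(e[gm_row, , 2]) / mean(e[gm_row, , 1])
  expect_equal(ratio, exp(-(0.014 - 0.006) / cfg$t2star_gm),
               tolerance = 1e-6)
})

test_that("sessions survive a write/read round trip as text + sidecar", {
  dir <- withr::local_tempdir()
  cfg <- noiseless_config(conditions = "center")
  par <- build_paradigm(1, seed = 5, conditions = "center")
  sess <- generate_session(list(par), config = cfg, seed = 5)
  write_session(sess, dir)
  back <- read_session(dir)
  expect_equal(back$runs[[1]]$ts$data, sess$runs[[1]]$ts$data,
               tolerance = 1e-9)
  expect_equal(back$runs[[1]]$events$onset, par$events$onset)
  expect_equal(back$meta$gm_depths, sess$gm_depths)
})
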