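#' Line-scanning time-series container
#'
#' A depth-by-time signal matrix sampled along the line (0.25 mm steps in
#' the laminar direction), with the gray-matter ribbon marked by an index
#' pair. Optionally carries uncombined multi-echo images.
#'
#' @param data depth x time numeric matrix (raw a.u. or percent signal).
#' @param tr sampling interval (s).
#' @param depth_positions positions along the line (mm).
#' @param gm_bounds integer pair: first and last row of the gray-matter
#'   ribbon (pial side first).
#' @param echoes optional depth x time x echo array.
#' @param echo_times echo times (s) matching the third axis of `echoes`.
#' @return Object of class `line_ts`.
#' @export
line_time_series <- function(data, tr, depth_positions, gm_bounds,
                             echoes = NULL, echo_times = NULL) {
  stopifnot(is.matrix(data), tr > 0,
            length(depth_positions) == nrow(data),
            length(gm_bounds) == 2,
            gm_bounds[1] >= 1, gm_bounds[2] <= nrow(data),
            gm_bounds[1] < gm_bounds[2])
  n_gm <- gm_bounds[2] - gm_bounds[1] + 1
  if (n_gm < 6 || n_gm > 10)
    warning("gray-matter ribbon outside the typical 6-10 sample range")
  structure(list(data = data, tr = tr, depth_positions = depth_positions,
                 gm_bounds = gm_bounds, echoes = echoes,
                 echo_times = echo_times),
            class = "line_ts")
}

#' Default configuration of the synthetic session generator
#'
#' Acquisition geometry and timing follow the line-scanning protocol this
#' package targets: TR 0.105 s, 0.25 mm laminar sampling, echo times
#' 6--38 ms, a 6--10 sample gray-matter ribbon inside a longer line with
#' outer-volume-suppressed surroundings, 7-min runs with 5 events per
#' condition and ISIs jittered in 14--24 s (mean 18 s).
#'
#' @param ... named overrides of any default.
#' @return Named list of generator settings.
#' @export
session_config <- function(...) {
  cfg <- list(
    tr = 0.105,
    run_length = 420,
    n_line = 24,               # voxels along the measured line
    depth_step_mm = 0.25,
    gm_start = 9,              # first gray-matter voxel (pial side)
    gm_size = 7,               # ribbon samples (6-10 across participants)
    baseline = 1000,           # raw signal level inside the ribbon (a.u.)
    ovs_factor = 0.05,         # residual signal level outside the ribbon
    noise_sd = 2,              # white/AR(1) noise sd (% signal per sample)
    ar1_rho = 0.3,
    drift_amp = 1,             # slow cosine drift amplitude (% signal)
    drift_periods = c(420, 210, 140),
    leakage_lambda = NULL,     # per-step drainage carry; NULL = off
    multi_echo = FALSE,
    echo_times = c(6, 14, 22, 30, 38) / 1000,
    t2star_gm = 0.033,
    t2star_out = 0.020,
    conditions = c("center", "medium", "large"),
    truth_params = list()
  )
  utils::modifyList(cfg, list(...))
}

# AR(1) + drift nuisance series in percent-signal units.
nuisance_series <- function(n, tr, cfg) {
  e <- stats::rnorm(n)
  ar <- as.numeric(stats::filter(e, cfg$ar1_rho, method = "recursive"))
  ar <- ar * sqrt(1 - cfg$ar1_rho^2)      # unit marginal sd
  t <- (seq_len(n) - 1) * tr
  drift <- 0
  for (p in cfg$drift_periods)
    drift <- drift + cos(2 * pi * t / p + stats::runif(1, 0, 2 * pi))
  cfg$noise_sd * ar + cfg$drift_amp * drift / max(1, length(cfg$drift_periods))
}

#' Generate a synthetic line-scanning session with known laminar ground truth
#'
#' For each paradigm (run), builds condition regressors by convolving the
#' event boxcars with the canonical HRF (unit single-event peak), multiplies
#' them by the condition's ground-truth laminar amplitude profile evaluated
#' at the ribbon's normalized depths, and embeds the resulting
#' percent-signal modulation in a raw signal line: full baseline inside the
#' gray-matter ribbon, strongly suppressed signal outside it (emulating
#' outer-volume suppression), plus AR(1) noise and slow cosine drift.
#' Optional per-step drainage leakage mixes deeper ribbon signal into
#' superficial bins before noise is added, and optional multi-echo mode
#' emits echo images scaled by `exp(-TE / T2*)` with a mono-exponential
#' T2* per depth.
#'
#' @param paradigms list of [build_paradigm()] objects, one per run.
#' @param truth named list of [make_ground_truth()] profiles per condition;
#'   built from `config$truth_params` when `NULL`.
#' @param config a [session_config()] list.
#' @param seed integer seed; all randomness derives from it.
#' @return Object of class `line_session`: list with `runs` (each a list of
#'   `ts` ([line_time_series()]) and `paradigm`), `truth`, `gm_depths`
#'   (normalized depth of each ribbon sample, 0 = pial), `config`, `seed`.
#' @export
generate_session <- function(paradigms, truth = NULL,
                             config = session_config(), seed = 1) {
  cfg <- config
  if (is.null(truth)) {
    truth <- lapply(cfg$conditions, make_ground_truth,
                    params = cfg$truth_params)
    names(truth) <- cfg$conditions
  }
  n_samples <- floor(cfg$run_length / cfg$tr)
  gm_idx <- seq(cfg$gm_start, length.out = cfg$gm_size)
  stopifnot(max(gm_idx) <= cfg$n_line)
  gm_depths <- (seq_len(cfg$gm_size) - 1) / (cfg$gm_size - 1)
  L <- if (!is.null(cfg$leakage_lambda)) {
    leakage_matrix(cfg$gm_size, cfg$leakage_lambda)
  } else NULL

  runs <- vector("list", length(paradigms))
  for (r in seq_along(paradigms)) {
    par <- paradigms[[r]]
    ev <- par$events
    # percent-signal modulation inside the ribbon: sum over conditions of
    # profile(depth) * regressor(t)
    psc_gm <- matrix(0, cfg$gm_size, n_samples)
    for (cond in names(truth)) {
      sel <- ev$trial_type == cond
      if (!any(sel)) next
      x <- convolve_events(ev$onset[sel], ev$duration[sel], n_samples, cfg$tr)
      psc_gm <- psc_gm + outer(truth[[cond]]$depth_fn(gm_depths), x)
    }
    if (!is.null(L)) psc_gm <- apply_leakage(psc_gm, L)

    base_line <- rep(cfg$baseline * cfg$ovs_factor, cfg$n_line)
    base_line[gm_idx] <- cfg$baseline
    psc <- matrix(0, cfg$n_line, n_samples)
    psc[gm_idx, ] <- psc_gm
    run_seed <- (as.integer(seed) %% 1000000L) * 1000L + r
    noise <- withr_seed(run_seed, {
      t(vapply(seq_len(cfg$n_line),
               function(i) nuisance_series(n_samples, cfg$tr, cfg),
               numeric(n_samples)))
    })
    raw <- base_line * (1 + (psc + noise) / 100)

    echoes <- NULL
    if (isTRUE(cfg$multi_echo)) {
      t2 <- rep(cfg$t2star_out, cfg$n_line)
      t2[gm_idx] <- cfg$t2star_gm
      echoes <- array(0, c(cfg$n_line, n_samples, length(cfg$echo_times)))
      for (e in seq_along(cfg$echo_times))
        echoes[, , e] <- raw * exp(-cfg$echo_times[e] / t2)
    }
    ts <- line_time_series(raw, cfg$tr,
                           depth_positions =
                             (seq_len(cfg$n_line) - 1) * cfg$depth_step_mm,
                           gm_bounds = range(gm_idx),
                           echoes = echoes, echo_times = cfg$echo_times)
    runs[[r]] <- list(ts = ts, paradigm = par)
  }
  structure(list(runs = runs, truth = truth, gm_depths = gm_depths,
                 config = cfg, seed = seed),
            class = "line_session")
}

#' Write / read a synthetic session as delimited text plus JSON sidecar
#'
#' Each run is stored as a tab-delimited depth x time matrix
#' (`run-<k>_line.tsv.gz`) and a BIDS-style `run-<k>_events.tsv`; a single
#' `session.json` sidecar records tr, depth positions, gray-matter bounds,
#' the seed and the ground-truth parameters.
#'
#' @param session a [generate_session()] object.
#' @param dir output directory (created if needed).
#' @return `read_session` returns a list with `runs` (each `ts` + `events`)
#'   and the sidecar metadata.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in seq_along(session$runs)) {
    run <- session$runs[[r]]
    con <- gzfile(file.path(dir, sprintf("run-%d_line.tsv.gz", r)), "w")
    utils::write.table(run$ts$data, con, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    close(con)
    write_events_tsv(run$paradigm,
                     file.path(dir, sprintf("run-%d_events.tsv", r)))
  }
  sidecar <- list(
    tr = session$config$tr,
    depth_positions = session$runs[[1]]$ts$depth_positions,
    gm_bounds = session$runs[[1]]$ts$gm_bounds,
    gm_depths = session$gm_depths,
    n_runs = length(session$runs),
    timing_variants = vapply(session$runs,
                             function(r) r$paradigm$timing_variant, 0),
    seed = session$seed,
    truth_params = session$truth[[1]]$params,
    conditions = names(session$truth))
  jsonlite::write_json(sidecar, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "session.json"),
                              simplifyVector = TRUE)
  runs <- lapply(seq_len(meta$n_runs), function(r) {
    mat <- as.matrix(utils::read.table(
      gzfile(file.path(dir, sprintf("run-%d_line.tsv.gz", r))), sep = "\t"))
    dimnames(mat) <- NULL
    ts <- line_time_series(mat, meta$tr, meta$depth_positions,
                           meta$gm_bounds)
    events <- read_events_tsv(file.path(dir,
                                        sprintf("run-%d_events.tsv", r)))
    list(ts = ts, events = events,
         timing_variant = meta$timing_variants[r])
  })
  list(runs = runs, meta = meta)
}
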