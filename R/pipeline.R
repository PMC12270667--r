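#' Per-condition response magnitude around the centre-response peak
#'
#' Finds the peak time of the depth-averaged centre-stimulus response and
#' averages every condition's depth-averaged response within +/- 1 s of it.
#' This is the magnitude summary used to confirm that the stimulus designed
#' to drive the target pRF hardest indeed evokes the largest response.
#'
#' @param means named list of per-condition depth x time matrices (from
#'   [epoch_and_average()]), containing `"center"`.
#' @param time epoch time axis (s).
#' @param half_width window half-width around the peak (s, default 1).
#' @return Named numeric vector of per-condition scalars; attribute
#'   `t_peak` gives the centre peak time.
#' @export
peak_window_response <- function(means, time, half_width = 1) {
  stopifnot("center" %in% names(means))
  center_tc <- colMeans(means[["center"]])
  t_peak <- time[which.max(center_tc)]
  lo <- t_peak - half_width; hi <- t_peak + half_width
  if (lo < min(time) || hi > max(time)) {
    warning("peak window clipped to the epoch")
    lo <- max(lo, min(time)); hi <- min(hi, max(time))
  }
  sel <- time >= lo & time <= hi
  out <- vapply(means, function(m) mean(colMeans(m)[sel]), 0)
  attr(out, "t_peak") <- t_peak
  out
}

#' Default end-to-end pipeline configuration
#'
#' @param ... named overrides (nested lists are merged).
#' @return Named list: cohort size, session generator settings
#'   ([session_config()]), paradigm settings, analysis settings (profile
#'   method, laminar-design parameters, deconvolution), and seed.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_participants = 11,
    n_variants = 2,
    session = session_config(),
    participant_gain_sd = 0.2,   # between-participant amplitude variability
    gm_sizes = 6:10,             # ribbon sizes sampled across participants
    profile_method = "template", # or "window"
    sigma_g = 0.12,
    drain_kind = "linear",
    tau = 0.25,
    deconvolve = FALSE,
    deconvolve_lambda = 0.3,
    seed = 1)
  utils::modifyList(cfg, list(...))
}

#' Run the full synthetic-session analysis pipeline
#'
#' simulate -> preprocess -> epoch -> re-grid -> depth profiles -> laminar
#' fits -> group statistics, for a cohort of synthetic participants.
#' Deterministic given the configuration (which includes the seed). Each
#' participant gets their own event timings (two timing variants), a ribbon
#' size drawn from `gm_sizes`, and a multiplicative response gain drawn
#' from `N(1, participant_gain_sd)`.
#'
#' @param config a [pipeline_config()] list.
#' @param progress print stage messages (default FALSE).
#' @return List of class `pipeline_result`: `participants` (per-participant
#'   session results: condition means on the 20-point grid, QC, profiles),
#'   `template`, `profiles` (long data.frame), `fits` (long data.frame with
#'   beta_context), `group` ([condition_contrast()] output),
#'   `peak_magnitudes`, `included`, and the `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), progress = FALSE) {
  cfg <- config
  say <- function(...) if (progress) message(...)
  conds <- cfg$session$conditions
  participants <- vector("list", cfg$n_participants)

  for (p in seq_len(cfg$n_participants)) {
    pseed <- (as.integer(cfg$seed) %% 100000L) * 1000L + p
    scfg <- cfg$session
    scfg$gm_size <- withr_seed(pseed * 7L,
                               sample(cfg$gm_sizes, 1))
    gain <- withr_seed(pseed * 11L,
                       stats::rnorm(1, 1, cfg$participant_gain_sd))
    tp <- scfg$truth_params
    tp$a <- (if (is.null(tp$a)) 1.5 else tp$a) * gain
    tp$p1 <- (if (is.null(tp$p1)) 1.0 else tp$p1) * gain
    tp$p2 <- (if (is.null(tp$p2)) 0.8 else tp$p2) * gain
    tp$m <- (if (is.null(tp$m)) 1.2 else tp$m) * gain
    tp$c <- (if (is.null(tp$c)) 0.3 else tp$c) * gain
    scfg$truth_params <- tp

    paradigms <- lapply(seq_len(cfg$n_variants), function(v)
      build_paradigm(variant = ifelse(v > 2, 2, v), seed = pseed + v,
                     conditions = conds,
                     run_length = scfg$run_length,
                     isi_min = scfg$isi_min %||% 14,
                     isi_max = scfg$isi_max %||% 24,
                     isi_mean = scfg$isi_mean %||% 18))
    say("participant ", p, ": simulating (ribbon ", scfg$gm_size,
        " samples)")
    session <- generate_session(paradigms, config = scfg, seed = pseed)
    runs <- preprocess_session(session)
    es <- epoch_and_average(runs, tr = scfg$tr)
    qc <- line_glm_quality(lapply(runs, `[[`, "data"),
                           lapply(runs, `[[`, "events"), scfg$tr,
                           runs[[1]]$gm_bounds, epoch_set = es)
    means20 <- lapply(es$means, select_gm_and_regrid, qc$shifted_bounds)
    participants[[p]] <- list(id = p, means20 = means20, time = es$time,
                              qc = qc, gm_size = scfg$gm_size, gain = gain,
                              truth = session$truth,
                              gm_depths = session$gm_depths)
  }

  say("building group template and profiles")
  template <- build_template(lapply(participants, function(pp)
    pp$means20[["center"]]))
  time <- participants[[1]]$time

  profiles <- do.call(rbind, lapply(participants, function(pp) {
    do.call(rbind, lapply(names(pp$means20), function(cond) {
      prof <- if (cfg$profile_method == "template") {
        template_weighting(pp$means20[[cond]], template)
      } else {
        window_average(pp$means20[[cond]], time)
      }
      cbind(data.frame(participant = pp$id, condition = cond),
            stats::setNames(as.data.frame(t(prof)), paste0("d", 1:20)))
    }))
  }))
  dcols <- grep("^d[0-9]+$", names(profiles))
  for (cond in unique(profiles$condition)) {
    sel <- profiles$condition == cond
    profiles[sel, dcols] <-
      normalize_across_participants(as.matrix(profiles[sel, dcols]))
  }

  say("fitting the laminar model")
  design <- build_design(sigma_g = cfg$sigma_g, drain_kind = cfg$drain_kind,
                         tau = cfg$tau)
  L <- if (isTRUE(cfg$deconvolve)) {
    leakage_matrix(20, cfg$deconvolve_lambda)
  } else NULL
  fits <- fit_cohort(profiles, design, deconvolve = L)
  group <- condition_contrast(fits)
  peaks <- colMeans(do.call(rbind, lapply(participants, function(pp)
    peak_window_response(pp$means20, time))))
  included <- vapply(participants, function(pp) isTRUE(pp$qc$included),
                     logical(1))
  structure(list(participants = participants, template = template,
                 profiles = profiles, fits = fits, group = group,
                 peak_magnitudes = peaks, included = included,
                 time = time, config = cfg),
            class = "pipeline_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write pipeline tables to tab-delimited files
#'
#' Writes `profiles.tsv` (participant, condition, 20 depth values),
#' `fits.tsv` (beta_context and fit quality) and `group.tsv` (descriptives)
#' into a directory.
#'
#' @param result a [run_pipeline()] object.
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_pipeline_tables <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(result$profiles, "profiles.tsv")
  wt(result$fits, "fits.tsv")
  wt(result$group$descriptives, "group.tsv")
  if (!is.null(result$group$pairwise)) wt(result$group$pairwise,
                                          "pairwise.tsv")
  invisible(dir)
}
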