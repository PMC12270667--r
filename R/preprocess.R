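#' Combine multi-echo line data into a single time series
#'
#' Two combination schemes over the echo axis:
#' \describe{
#'   \item{`sos`}{root-sum-of-squares per sample, `sqrt(sum_e S_e^2)` —
#'     maximises signal stability without needing a relaxometry fit.}
#'   \item{`t2star`}{weighted sum `sum_e w_e S_e` with
#'     `w_e \propto TE_e exp(-TE_e / T2*)` (weights normalised to 1), the
#'     BOLD-sensitivity-optimal weighting; `T2*` is estimated per depth by a
#'     log-linear fit of the time-averaged echo images against echo time.}
#' }
#'
#' @param echoes depth x time x echo array.
#' @param echo_times echo times (s), one per echo.
#' @param method `"sos"` or `"t2star"`.
#' @return List with `data` (depth x time matrix) and, for `t2star`, the
#'   per-depth `t2star` estimates (s).
#' @export
combine_echoes <- function(echoes, echo_times, method = c("sos", "t2star")) {
  method <- match.arg(method)
  stopifnot(length(dim(echoes)) == 3,
            dim(echoes)[3] == length(echo_times))
  if (method == "sos") {
    if (dim(echoes)[3] == 1) return(list(data = echoes[, , 1]))
    return(list(data = sqrt(apply(echoes^2, c(1, 2), sum))))
  }
  stopifnot(length(echo_times) >= 2)
  mean_img <- apply(echoes, c(1, 3), mean)   # depth x echo
  n_depth <- nrow(mean_img)
  t2 <- rep(NA_real_, n_depth)
  ok <- apply(mean_img > 0, 1, all)
  for (i in which(ok)) {
    fit <- stats::lm.fit(cbind(1, echo_times), log(mean_img[i, ]))
    slope <- fit$coefficients[2]
    if (is.finite(slope) && slope < 0) t2[i] <- -1 / slope
  }
  if (any(is.na(t2))) {
    warning("non-positive mean signal in log-linear T2* fit; ",
            "falling back to the global estimate for affected depths")
    t2[is.na(t2)] <- stats::median(t2, na.rm = TRUE)
    if (all(is.na(t2))) stop("T2* estimation failed at every depth")
  }
  out <- matrix(0, n_depth, dim(echoes)[2])
  for (i in seq_len(n_depth)) {
    w <- echo_times * exp(-echo_times / t2[i])
    w <- w / sum(w)
    out[i, ] <- drop(echoes[i, , ] %*% w)
  }
  list(data = out, t2star = t2)
}

#' Savitzky-Golay smoothing of a time series
#'
#' Local least-squares polynomial smoothing with the acquisition protocol's
#' 31-sample, 3rd-order kernel, using mirrored edges so the output has the
#' input's length. Applied row-wise when given a matrix.
#'
#' @param x numeric vector, or depth x time matrix (smoothed along time).
#' @param window filter length in samples (odd; default 31).
#' @param order polynomial order (default 3).
#' @return Smoothed series, same shape as `x`.
#' @export
savgol_smooth <- function(x, window = 31, order = 3) {
  if (is.matrix(x))
    return(t(apply(x, 1, savgol_smooth, window = window, order = order)))
  n <- length(x)
  if (window >= n) stop("Savitzky-Golay window must be shorter than series")
  stopifnot(window %% 2 == 1, order < window)
  half <- (window - 1) / 2
  coefs <- signal::sgolay(p = order, n = window)[half + 1, ]
  padded <- c(x[(half + 1):2], x, x[(n - 1):(n - half)])
  out <- stats::filter(padded, rev(coefs), sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

#' Percent-signal-change scaling
#'
#' Per depth row, `100 * (s - median(s)) / median(s)`. The temporal median
#' is a robust baseline for sparse event-related designs where the signal
#' sits at rest most of the time.
#'
#' @param x numeric vector, or depth x time matrix (scaled per row).
#' @return Percent-signal series, same shape.
#' @export
percent_signal_change <- function(x) {
  if (is.matrix(x))
    return(t(apply(x, 1, percent_signal_change)))
  m <- stats::median(x)
  if (m == 0) stop("zero median baseline in percent-signal scaling")
  if (m < 0) stop("negative baseline in percent-signal scaling")
  100 * (x - m) / m
}

#' Epoch a run around stimulus events and average per condition
#'
#' Cuts a window from 2 s before to 14 s after each stimulus onset
#' (fixed length `round(16 / tr)` samples, onset aligned to the nearest
#' sample at or before `onset - 2`), baseline-corrects each epoch by its
#' pre-onset mean, then averages — first element-wise across runs sharing a
#' timing variant (their event timings are identical), then across events —
#' giving one mean evoked response per condition.
#'
#' @param runs list of runs, each a list with `data` (depth x time percent
#'   signal), `events` (data.frame `onset`, `duration`, `trial_type`) and
#'   `variant` (timing-variant id).
#' @param tr sampling interval (s).
#' @param window epoch window relative to onset (s), default `c(-2, 14)`.
#' @return List of class `epoch_set`: `epochs` (list of depth x n_t
#'   matrices, one per variant x event, baseline-corrected), `condition`
#'   and `variant` labels per epoch, `time` (epoch time axis, s), `means`
#'   (named list of per-condition mean depth x n_t matrices), and
#'   `n_dropped` (events whose window fell outside the run).
#' @export
epoch_and_average <- function(runs, tr, window = c(-2, 14)) {
  stopifnot(window[1] < 0, window[2] > 0)
  n_t <- round((window[2] - window[1]) / tr)
  n_pre <- round(-window[1] / tr)
  time <- window[1] + (seq_len(n_t) - 1) * tr

  variants <- unique(vapply(runs, function(r) r$variant, 0))
  epochs <- list(); cond_lab <- character(0); var_lab <- numeric(0)
  n_dropped <- 0
  for (v in variants) {
    vruns <- runs[vapply(runs, function(r) r$variant, 0) == v]
    ev <- vruns[[1]]$events    # identical timing within a variant
    for (k in seq_len(nrow(ev))) {
      i0 <- floor((ev$onset[k] + window[1]) / tr) + 1
      i1 <- i0 + n_t - 1
      if (i0 < 1 || any(vapply(vruns, function(r) ncol(r$data), 0) < i1)) {
        n_dropped <- n_dropped + 1
        warning("dropping truncated epoch at onset ", ev$onset[k], " s")
        next
      }
      # average across runs with identical timing first
      ep <- Reduce(`+`, lapply(vruns, function(r) r$data[, i0:i1])) /
        length(vruns)
      ep <- ep - rowMeans(ep[, seq_len(n_pre), drop = FALSE])
      epochs[[length(epochs) + 1]] <- ep
      cond_lab <- c(cond_lab, ev$trial_type[k])
      var_lab <- c(var_lab, v)
    }
  }
  means <- lapply(split(seq_along(epochs), cond_lab), function(idx)
    Reduce(`+`, epochs[idx]) / length(idx))
  structure(list(epochs = epochs, condition = cond_lab, variant = var_lab,
                 time = time, window = window, means = means,
                 n_dropped = n_dropped),
            class = "epoch_set")
}

# Convenience: turn a line_session (or read_session output) into the run
# list epoch_and_average expects, running echo combination, smoothing and
# percent-signal scaling per run.
#' Preprocess the runs of a session into percent-signal matrices
#'
#' Echo combination (when multi-echo data are present), Savitzky-Golay
#' smoothing (31 samples, 3rd order) and percent-signal-change scaling,
#' per run.
#'
#' @param session a [generate_session()] or [read_session()] object.
#' @param echo_method `"sos"` or `"t2star"` (used only for multi-echo runs).
#' @param smooth logical; apply the Savitzky-Golay filter (default TRUE).
#' @return List of runs (`data`, `events`, `variant`, `gm_bounds`, `tr`)
#'   ready for [epoch_and_average()].
#' @export
preprocess_session <- function(session, echo_method = "sos", smooth = TRUE) {
  lapply(session$runs, function(run) {
    ts <- run$ts
    dat <- if (!is.null(ts$echoes)) {
      combine_echoes(ts$echoes, ts$echo_times, echo_method)$data
    } else ts$data
    if (smooth) dat <- savgol_smooth(dat)
    dat <- percent_signal_change(dat)
    events <- if (!is.null(run$paradigm)) run$paradigm$events else run$events
    variant <- if (!is.null(run$paradigm)) {
      run$paradigm$timing_variant
    } else run$timing_variant
    list(data = dat, events = events, variant = variant,
         gm_bounds = ts$gm_bounds, tr = ts$tr)
  })
}

#' Restrict to the gray-matter ribbon and re-grid to the standard depth axis
#'
#' Maps the ribbon samples to normalized depth (0 = pial, 1 = white matter)
#' and linearly interpolates each time point onto `n_out` evenly spaced
#' depths, standardising profiles across participants whose ribbons span
#' 6--10 native samples.
#'
#' @param x depth x time matrix (or depth vector) over the full line.
#' @param gm_bounds integer pair delimiting the ribbon (pial side first).
#' @param n_out output grid size (default 20).
#' @param method interpolation method: `"linear"` (default) or `"nearest"`.
#' @return `n_out` x time matrix (or length-`n_out` vector).
#' @export
select_gm_and_regrid <- function(x, gm_bounds, n_out = 20,
                                 method = c("linear", "nearest")) {
  method <- match.arg(method)
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1)
  ribbon <- x[gm_bounds[1]:gm_bounds[2], , drop = FALSE]
  m <- nrow(ribbon)
  if (m < 2) stop("gray-matter ribbon has fewer than 2 samples")
  if (m < 6 || m > 10)
    warning("gray-matter ribbon outside the recommended 6-10 sample range")
  d_in <- (seq_len(m) - 1) / (m - 1)
  d_out <- seq(0, 1, length.out = n_out)
  out <- apply(ribbon, 2, function(col)
    stats::approx(d_in, col, xout = d_out,
                  method = if (method == "linear") "linear" else "constant",
                  rule = 2)$y)
  out <- matrix(out, nrow = n_out)
  if (vec) drop(out) else out
}

#' GLM-based quality assessment along the line
#'
#' Regresses every line position's time course on an HRF-convolved
#' centre-stimulus regressor (plus intercept) and reports variance explained
#' along the line, confirming that responses localise to the targeted
#' ribbon. Optionally searches integer ribbon shifts within `max_shift`
#' samples for the placement maximising mean ribbon r². When the epoch-set
#' condition means are supplied, also evaluates the two inclusion criteria:
#' the centre response (5--7 s window, depth-averaged) must exceed every
#' other condition, and the centre depth profile must show the draining-vein
#' signature (superficial third above the deep third).
#'
#' @param psc depth x time percent-signal matrix over the full line, or a
#'   list of such matrices (one per run; r-squared is averaged over runs).
#' @param events event data.frame with centre-stimulus rows
#'   (`trial_type == "center"`), or a list of them matching `psc`.
#' @param tr sampling interval (s).
#' @param gm_bounds ribbon index pair.
#' @param epoch_set optional [epoch_and_average()] result for the inclusion
#'   decision.
#' @param max_shift ribbon shift search radius in samples (default 2).
#' @param shift_margin minimum absolute gain in mean ribbon r-squared
#'   required before a nonzero shift is accepted (default 0.01); guards
#'   against spurious shifts on a flat, noise-dominated r-squared landscape.
#' @return List: `r2` (per line position), `shift` (selected ribbon offset),
#'   `shifted_bounds`, and `included` (logical, `NA` without `epoch_set`).
#' @export
line_glm_quality <- function(psc, events, tr, gm_bounds,
                             epoch_set = NULL, max_shift = 2,
                             shift_margin = 0.01) {
  if (!is.list(psc)) { psc <- list(psc); events <- list(events) }
  one_r2 <- function(mat, ev) {
    sel <- ev$trial_type == "center"
    stopifnot(any(sel))
    x <- convolve_events(ev$onset[sel], ev$duration[sel], ncol(mat), tr)
    X <- cbind(1, x)
    apply(mat, 1, function(y) {
      ss_tot <- sum((y - mean(y))^2)
      if (ss_tot == 0) return(0)    # flat (e.g. fully suppressed) position
      fit <- stats::lm.fit(X, y)
      1 - sum(fit$residuals^2) / ss_tot
    })
  }
  r2 <- rowMeans(mapply(one_r2, psc, events))
  shifts <- -max_shift:max_shift
  shifts <- shifts[gm_bounds[1] + shifts >= 1 &
                     gm_bounds[2] + shifts <= nrow(psc[[1]])]
  mean_r2 <- vapply(shifts, function(s)
    mean(r2[(gm_bounds[1] + s):(gm_bounds[2] + s)]), 0)
  shift <- shifts[which.max(mean_r2)]
  if (mean_r2[which.max(mean_r2)] - mean_r2[shifts == 0] < shift_margin)
    shift <- 0
  shifted <- gm_bounds + shift

  included <- NA
  if (!is.null(epoch_set)) {
    t_sel <- epoch_set$time >= 5 & epoch_set$time <= 7
    mag <- vapply(epoch_set$means, function(m)
      mean(select_gm_and_regrid(m, shifted)[, t_sel]), 0)
    prof <- rowMeans(select_gm_and_regrid(
      epoch_set$means[["center"]], shifted)[, t_sel, drop = FALSE])
    third <- floor(length(prof) / 3)
    drain_ok <- mean(prof[seq_len(third)]) >
      mean(prof[(length(prof) - third + 1):length(prof)])
    center_max <- all(mag["center"] >= mag[names(mag) != "center"])
    included <- center_max && drain_ok
  }
  list(r2 = r2, shift = shift, shifted_bounds = shifted, included = included)
}
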