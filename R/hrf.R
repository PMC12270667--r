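#' Canonical double-gamma haemodynamic response function
#'
#' Two gamma-variate components: a positive response peaking at 6 s and an
#' undershoot peaking at 16 s with amplitude ratio 1/6. Each component is a
#' gamma-variate `t^a * exp(-t)` whose mode sits exactly at its peak time;
#' the combined kernel is rescaled to unit peak and sampled at the
#' acquisition interval.
#'
#' @param tr sampling interval (s).
#' @param duration kernel length (s), default 32.
#' @return Numeric vector, `floor(duration / tr) + 1` samples starting at
#'   `t = 0` (where the kernel is 0).
#' @export
double_gamma_hrf <- function(tr, duration = 32) {
  stopifnot(tr > 0)
  t <- seq(0, duration, by = tr)
  h <- hrf_continuous(t)
  h / max(h)
}

# Closed-form continuous kernel (unnormalized): gamma-variates with modes at
# 6 s (peak) and 16 s (undershoot), unit-peak each, ratio 1/6.
hrf_continuous <- function(t) {
  peak <- (t / 6)^6 * exp(-(t - 6))
  under <- (t / 16)^16 * exp(-(t - 16))
  out <- peak - under / 6
  out[t < 0] <- 0
  out
}

#' Convolve an event design with the HRF
#'
#' Builds a boxcar for the given events on a regular time grid and convolves
#' it with the canonical HRF. The result is scaled so that the response to a
#' single event of the given duration peaks at 1, making amplitudes
#' interpretable as per-event peak percent signal change.
#'
#' @param onsets,durations event timings (s).
#' @param n_samples length of the output time series.
#' @param tr sampling interval (s).
#' @param normalize if `TRUE` (default), scale to unit single-event peak.
#' @return Numeric regressor of length `n_samples`.
#' @export
convolve_events <- function(onsets, durations, n_samples, tr,
                            normalize = TRUE) {
  hrf <- double_gamma_hrf(tr)
  box <- numeric(n_samples)
  for (k in seq_along(onsets)) {
    i0 <- floor(onsets[k] / tr) + 1
    i1 <- min(floor((onsets[k] + durations[k]) / tr), n_samples)
    if (i0 <= n_samples) box[i0:min(i1, n_samples)] <- 1
  }
  out <- stats::convolve(box, rev(hrf), type = "open")[seq_len(n_samples)]
  if (normalize) {
    single <- stats::convolve(c(rep(1, max(1, round(durations[1] / tr))),
                                numeric(length(hrf))),
                              rev(hrf), type = "open")
    out <- out / max(single)
  }
  out
}
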