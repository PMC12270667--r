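#' Build the group response template from centre-stimulus responses
#'
#' The template is the centre-stimulus evoked response averaged over
#' participants and over the 20 depths — a reference time course against
#' which depth-dependent responses to the other stimuli are weighted. A
#' template is preferable to a fixed time window because response latency
#' varies across participants.
#'
#' @param center_responses list of depth x time matrices (one per
#'   participant), baseline-corrected percent signal.
#' @return Numeric template time course.
#' @export
build_template <- function(center_responses) {
  stopifnot(length(center_responses) >= 1)
  tmpl <- Reduce(`+`, lapply(center_responses, colMeans)) /
    length(center_responses)
  if (max(abs(tmpl)) < .Machine$double.eps^0.5)
    warning("template is (near) zero; participants' responses cancel")
  tmpl
}

#' Collapse depth-resolved time courses onto a template (depth profile)
#'
#' For each depth `d`, computes the template-weighted average
#' \deqn{profile_d = \frac{\sum_t h_d(t)\, h_T(t)}{\sum_t h_T(t)}}
#' where `h_d` is the depth's evoked time course and `h_T` the group centre
#' template. The result is a scaling factor per depth: large when the
#' characteristic centre-response shape is strongly expressed at that
#' depth, negative when the depth responds with opposite sign.
#'
#' @param set depth x time matrix of evoked time courses.
#' @param template time course from [build_template()] (same time axis).
#' @return Numeric depth profile (one value per row of `set`).
#' @export
template_weighting <- function(set, template) {
  stopifnot(is.matrix(set), ncol(set) == length(template))
  s <- sum(template)
  if (abs(s) < .Machine$double.eps^0.5) stop("degenerate template")
  drop(set %*% template) / s
}

#' Average evoked responses within a fixed post-onset window
#'
#' The window-average alternative to template weighting: per depth, the mean
#' over samples falling in the given post-onset interval (default 5--7 s,
#' around the haemodynamic peak).
#'
#' @param set depth x time matrix.
#' @param time epoch time axis (s, relative to onset).
#' @param window inclusive window (s), default `c(5, 7)`.
#' @return Numeric depth profile.
#' @export
window_average <- function(set, time, window = c(5, 7)) {
  sel <- time >= window[1] & time <= window[2]
  if (!any(sel)) stop("window contains no samples")
  rowMeans(set[, sel, drop = FALSE])
}

#' Remove between-participant offsets from depth profiles
#'
#' Subtracts each participant's own mean across depth and adds back the
#' grand mean, reducing between-participant level noise while preserving
#' the group mean exactly. Idempotent.
#'
#' @param profiles participant x depth numeric matrix.
#' @return Matrix of the same shape.
#' @export
normalize_across_participants <- function(profiles) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 1)
  grand <- mean(profiles)
  profiles - rowMeans(profiles) + grand
}

#' Group depth-by-time matrix with pointwise 95% confidence intervals
#'
#' @param sets list of depth x time matrices, one per participant.
#' @return List: `mean` (depth x time), `ci_lower`, `ci_upper`
#'   (mean +/- 1.96 * SEM); CI members are `NULL` with a warning when only
#'   one participant is supplied.
#' @export
depth_by_time <- function(sets) {
  n <- length(sets)
  stopifnot(n >= 1)
  m <- Reduce(`+`, sets) / n
  if (n < 2) {
    warning("confidence interval undefined for a single participant")
    return(list(mean = m, ci_lower = NULL, ci_upper = NULL))
  }
  sq <- Reduce(`+`, lapply(sets, function(s) (s - m)^2))
  sem <- sqrt(sq / (n - 1)) / sqrt(n)
  list(mean = m, ci_lower = m - 1.96 * sem, ci_upper = m + 1.96 * sem)
}
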