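#' Design matrix of the descriptive laminar model
#'
#' Six regressors over the standardized depth grid, in fixed column order
#' `[intercept, drain, G_sup, G_deep, dG_sup, dG_deep]`:
#' \itemize{
#'   \item an intercept of ones;
#'   \item a draining-vein term — either the linear ramp `1 - d` (largest at
#'     the pial surface, where venous carry-over accumulates) or a negative
#'     exponential `exp(-d / tau)` increasing toward the surface — zero-meaned
#'     so it carries no offset;
#'   \item unit-maximum Gaussians peaking at 25% and 75% cortical depth,
#'     the termination sites of descending (contextual) connections;
#'   \item their analytic depth-derivatives, scaled to unit maximum absolute
#'     value, letting each peak shift slightly to absorb individual
#'     anatomical variability.
#' }
#' The last four columns form the contextual block summarised by
#' [beta_context()].
#'
#' @param n_depth grid size (default 20).
#' @param sigma_g Gaussian width in normalized depth (default 0.12).
#' @param drain_kind `"linear"` or `"exponential"`.
#' @param tau exponential drain length constant (default 0.25).
#' @return Object of class `laminar_design`: list with `X` (n_depth x 6
#'   matrix with named columns), `depth` grid, and the parameters.
#' @export
build_design <- function(n_depth = 20, sigma_g = 0.12,
                         drain_kind = c("linear", "exponential"),
                         tau = 0.25) {
  drain_kind <- match.arg(drain_kind)
  stopifnot(sigma_g > 0, sigma_g < 0.5)
  d <- seq(0, 1, length.out = n_depth)
  g <- function(mu) exp(-(d - mu)^2 / (2 * sigma_g^2))
  dg <- function(mu) {
    v <- -(d - mu) / sigma_g^2 * exp(-(d - mu)^2 / (2 * sigma_g^2))
    v / max(abs(v))
  }
  drain <- if (drain_kind == "linear") 1 - d else exp(-d / tau)
  drain <- drain - mean(drain)
  X <- cbind(intercept = 1, drain = drain,
             G_sup = g(0.25), G_deep = g(0.75),
             dG_sup = dg(0.25), dG_deep = dg(0.75))
  structure(list(X = X, depth = d, sigma_g = sigma_g,
                 drain_kind = drain_kind, tau = tau),
            class = "laminar_design")
}

#' Fit the laminar model to a depth profile by ordinary least squares
#'
#' @param profile numeric depth profile (length matching the design grid).
#' @param design a [build_design()] object.
#' @param condition optional condition label carried into the result.
#' @return Object of class `laminar_fit`: `betas` (named, length 6),
#'   `residuals`, `fitted`, `r2`, `beta_context` (sum of the last four
#'   coefficients), `condition`.
#' @export
fit_profile <- function(profile, design, condition = NA_character_) {
  X <- design$X
  stopifnot(length(profile) == nrow(X))
  if (qr(X)$rank < ncol(X)) stop("rank-deficient laminar design")
  fit <- stats::lm.fit(X, profile)
  betas <- fit$coefficients
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((profile - mean(profile))^2)
  structure(list(betas = betas, residuals = fit$residuals,
                 fitted = drop(X %*% betas),
                 r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 beta_context = sum(betas[3:6]),
                 condition = condition),
            class = "laminar_fit")
}

#' Contextual summary statistic of a laminar fit
#'
#' Sum of the coefficients of the contextual block — the two depth Gaussians
#' (peaks at 25% and 75% depth) and their derivatives, excluding intercept
#' and drain term. Positive values indicate a bimodal, context-like laminar
#' profile; negative values a profile anti-correlated with it.
#'
#' @param fit a [fit_profile()] object (or a length-6 coefficient vector).
#' @return Scalar beta_context.
#' @export
beta_context <- function(fit) {
  betas <- if (inherits(fit, "laminar_fit")) fit$betas else fit
  stopifnot(length(betas) == 6)
  sum(betas[3:6])
}

#' Group comparison of contextual coefficients across conditions
#'
#' Descriptives (mean, SEM) per condition, a one-way ANOVA with partial
#' eta-squared, and pairwise paired t-tests with Holm correction plus
#' paired Cohen's d. Thin wrappers over the standard routines; with fewer
#' than two participants only descriptives are returned.
#'
#' @param fits data.frame with columns `participant`, `condition`,
#'   `beta_context`.
#' @return List: `descriptives` data.frame, `anova` (F, df, p, partial
#'   eta-squared), `pairwise` data.frame (mean difference, t, df, raw and
#'   Holm-adjusted p, Cohen's d).
#' @export
condition_contrast <- function(fits) {
  stopifnot(all(c("participant", "condition", "beta_context") %in%
                  names(fits)))
  desc <- do.call(rbind, lapply(split(fits, fits$condition), function(g)
    data.frame(condition = g$condition[1], n = nrow(g),
               mean = mean(g$beta_context),
               sem = stats::sd(g$beta_context) / sqrt(nrow(g)))))
  rownames(desc) <- NULL
  n_per <- table(fits$condition)
  if (any(n_per < 2))
    return(list(descriptives = desc, anova = NULL, pairwise = NULL))

  fits$condition <- factor(fits$condition)
  av <- stats::aov(beta_context ~ condition, data = fits)
  s <- summary(av)[[1]]
  anova_tab <- list(F = s[["F value"]][1],
                    df = c(s[["Df"]][1], s[["Df"]][2]),
                    p = s[["Pr(>F)"]][1],
                    partial_eta2 = s[["Sum Sq"]][1] /
                      (s[["Sum Sq"]][1] + s[["Sum Sq"]][2]))

  conds <- levels(fits$condition)
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    a <- fits[fits$condition == pr[1], ]
    b <- fits[fits$condition == pr[2], ]
    a <- a[order(a$participant), ]; b <- b[order(b$participant), ]
    paired <- nrow(a) == nrow(b) && all(a$participant == b$participant)
    tt <- tryCatch(
      stats::t.test(a$beta_context, b$beta_context, paired = paired),
      error = function(e) list(statistic = NA_real_, parameter = NA_real_,
                               p.value = NA_real_))
    dvec <- if (paired) a$beta_context - b$beta_context else NULL
    d <- if (paired) mean(dvec) / stats::sd(dvec) else {
      (mean(a$beta_context) - mean(b$beta_context)) /
        sqrt((stats::var(a$beta_context) + stats::var(b$beta_context)) / 2)
    }
    data.frame(a = pr[1], b = pr[2],
               diff = mean(a$beta_context) - mean(b$beta_context),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, cohens_d = d, paired = paired)
  }))
  pw$p_holm <- stats::p.adjust(pw$p, method = "holm")
  list(descriptives = desc, anova = anova_tab, pairwise = pw)
}

#' Simulate a cohort of noisy laminar profiles with known ground truth
#'
#' Draws per-participant depth profiles on the 20-point grid from the
#' condition ground-truth shapes: each participant scales the profile by a
#' multiplicative gain `N(1, gain_sd)` and adds i.i.d. measurement noise
#' `N(0, noise_sd)` per depth. Optionally passes profiles through the
#' drainage forward model first (so deconvolution can be exercised on
#' cohorts). Used for Monte-Carlo calibration of the laminar model.
#'
#' @param n_participants cohort size (default 11).
#' @param conditions condition labels (default center and large).
#' @param noise_sd per-depth measurement noise sd (% signal, default 0.2).
#' @param gain_sd between-participant gain sd (default 0.2).
#' @param truth_params overrides for [make_ground_truth()].
#' @param leakage optional [leakage_matrix()] (20 x 20) applied to each
#'   profile.
#' @param n_depth grid size (default 20).
#' @param seed integer seed.
#' @return data.frame: `participant`, `condition`, and `d1..d<n>` profile
#'   columns; attribute `profiles` holds the matrix rows.
#' @export
simulate_profile_cohort <- function(n_participants = 11,
                                    conditions = c("center", "large"),
                                    noise_sd = 0.2, gain_sd = 0.2,
                                    truth_params = list(),
                                    leakage = NULL, n_depth = 20,
                                    seed = 1) {
  grid_truth <- lapply(conditions, function(cond)
    ground_truth_on_grid(make_ground_truth(cond, truth_params),
                         n_out = n_depth))
  names(grid_truth) <- conditions
  rows <- withr_seed(seed, {
    out <- list()
    for (p in seq_len(n_participants)) {
      gain <- stats::rnorm(1, 1, gain_sd)
      for (cond in conditions) {
        prof <- gain * grid_truth[[cond]]
        if (!is.null(leakage)) prof <- apply_leakage(prof, leakage)
        prof <- prof + stats::rnorm(n_depth, 0, noise_sd)
        out[[length(out) + 1]] <- list(participant = p, condition = cond,
                                       profile = prof)
      }
    }
    out
  })
  df <- data.frame(participant = vapply(rows, `[[`, 0, "participant"),
                   condition = vapply(rows, `[[`, "", "condition"))
  mat <- do.call(rbind, lapply(rows, `[[`, "profile"))
  colnames(mat) <- paste0("d", seq_len(n_depth))
  cbind(df, as.data.frame(mat))
}

#' Fit the laminar model to every profile of a cohort table
#'
#' @param cohort a [simulate_profile_cohort()] data.frame (or any table with
#'   `participant`, `condition` and `d1..dN` columns).
#' @param design a [build_design()] object.
#' @param deconvolve optional [leakage_matrix()]; when supplied each profile
#'   is drainage-deconvolved before fitting.
#' @return data.frame `participant`, `condition`, `beta_context`, `r2`.
#' @export
fit_cohort <- function(cohort, design, deconvolve = NULL) {
  dcols <- grep("^d[0-9]+$", names(cohort))
  out <- lapply(seq_len(nrow(cohort)), function(i) {
    prof <- as.numeric(cohort[i, dcols])
    if (!is.null(deconvolve)) prof <- deconvolve_profile(prof, deconvolve)
    fit <- fit_profile(prof, design, cohort$condition[i])
    data.frame(participant = cohort$participant[i],
               condition = cohort$condition[i],
               beta_context = fit$beta_context, r2 = fit$r2)
  })
  do.call(rbind, out)
}
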