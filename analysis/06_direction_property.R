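#!/usr/bin/env Rscript
# Monte-Carlo check of the headline direction: across seeded synthetic
# cohorts (n = 11), the large annulus should carry a higher mean
# beta_context than the centre stimulus, robustly to the drain term's form
# and to drainage deconvolution.

suppressPackageStartupMessages(library(lamline))
out_dir <- "results/group"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

des_lin <- build_design()
des_exp <- build_design(drain_kind = "exponential")
L <- leakage_matrix(20, 0.3)
n_rep <- 200

diff_of <- function(fits) {
  m <- tapply(fits$beta_context, fits$condition, mean)
  m[["large"]] - m[["center"]]
}
diffs <- matrix(NA_real_, n_rep, 4,
                dimnames = list(NULL, c("linear", "exponential",
                                        "leaked_raw", "leaked_deconv")))
for (r in seq_len(n_rep)) {
  cohort <- simulate_profile_cohort(seed = r)
  leaked <- simulate_profile_cohort(seed = r, leakage = L)
  diffs[r, "linear"] <- diff_of(fit_cohort(cohort, des_lin))
  diffs[r, "exponential"] <- diff_of(fit_cohort(cohort, des_exp))
  diffs[r, "leaked_raw"] <- diff_of(fit_cohort(leaked, des_lin))
  diffs[r, "leaked_deconv"] <- diff_of(fit_cohort(leaked, des_lin,
                                                  deconvolve = L))
}
for (v in colnames(diffs))
  cat(sprintf(
    "%-14s mean diff %.2f; large > centre in %.1f%% of %d cohorts\n",
    v, mean(diffs[, v]), 100 * mean(diffs[, v] > 0), n_rep))
utils::write.table(as.data.frame(diffs),
                   file.path(out_dir, "direction_montecarlo.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("Monte-Carlo table written to", out_dir, "\n")
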