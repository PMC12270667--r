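#!/usr/bin/env Rscript
# Preprocess the example session written by 02_simulate_session.R:
# Savitzky-Golay smoothing (31 samples, 3rd order), percent-signal-change
# scaling, epoching (-2..14 s around onsets, baseline-corrected), GLM
# quality assessment along the line, and re-gridding of the condition mean
# responses to the standard 20-point depth axis.

suppressPackageStartupMessages(library(lamline))
in_dir <- "results/session_example"
out_dir <- "results/preprocessed"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
if (!file.exists(file.path(in_dir, "session.json")))
  stop("run analysis/02_simulate_session.R first")

session <- read_session(in_dir)
runs <- preprocess_session(session)
tr <- runs[[1]]$tr
es <- epoch_and_average(runs, tr = tr)
cat(sprintf("epoched %d events into %d-sample windows (%d dropped)\n",
            length(es$epochs), length(es$time), es$n_dropped))
for (cond in names(es$means))
  cat(sprintf("  %s: %d epochs\n", cond, sum(es$condition == cond)))

qc <- line_glm_quality(lapply(runs, `[[`, "data"),
                       lapply(runs, `[[`, "events"), tr,
                       runs[[1]]$gm_bounds, epoch_set = es)
cat(sprintf("centre-stimulus GLM: mean ribbon r2 %.3f, shift %d, %s\n",
            mean(qc$r2[qc$shifted_bounds[1]:qc$shifted_bounds[2]]),
            qc$shift,
            if (qc$included) "session included" else "session excluded"))
utils::write.table(
  data.frame(position = seq_along(qc$r2), r2 = qc$r2),
  file.path(out_dir, "line_glm_r2.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

for (cond in names(es$means)) {
  m20 <- select_gm_and_regrid(es$means[[cond]], qc$shifted_bounds)
  utils::write.table(m20,
                     file.path(out_dir, paste0(cond, "_evoked_20depth.tsv")),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}
cat("20-depth evoked responses written to", out_dir, "\n")
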