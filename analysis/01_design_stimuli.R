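#!/usr/bin/env Rscript
# Participant-specific stimulus design from pRF estimates.
#
# Filters a table of candidate pRFs by the selection criteria (eccentricity
# band 1.5-3 dva, >= 1 dva from the vertical meridian, r2 > 0.55,
# sigma1 > 0.50 dva), then derives for the best candidate the three
# stimuli: the centre checkerboard at the size-tuning optimum, the largest
# non-occluded 2-dva annulus, and the medium annulus halfway between them.

suppressPackageStartupMessages(library(lamline))
out_dir <- "results/stimulus_design"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
set.seed(1)

# candidate table as a pRF-mapping session would deliver it (synthetic)
n <- 40
cand <- data.frame(
  id = seq_len(n),
  x = runif(n, -4, 4), y = runif(n, -3, 3),
  sigma1 = runif(n, 0.3, 1.2))
cand$sigma2 <- cand$sigma1 * runif(n, 2, 4)
cand$amp_act <- 1
cand$amp_norm <- 0.05
cand$b <- 50; cand$d <- 500
cand$r2 <- runif(n, 0.3, 0.9)
cand$eccentricity <- sqrt(cand$x^2 + cand$y^2)
cand$merid_dist <- abs(cand$x)

surviving <- filter_prf_candidates(cand)
cat(sprintf("%d of %d candidate pRFs survive the selection filter\n",
            nrow(surviving), nrow(cand)))
utils::write.table(surviving, file.path(out_dir, "prf_candidates.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

best <- surviving[which.max(surviving$r2), ]
prf <- prf_params(best$x, best$y, best$sigma1, best$sigma2,
                  best$amp_act, best$amp_norm, best$b, best$d, best$r2)
screen <- screen_geometry()

set <- suppressWarnings(design_stimulus_set(prf, screen))
mk <- spatial_profile_markers(prf)
cat(sprintf("target pRF at (%.2f, %.2f), sigma1 %.2f dva\n",
            prf$x, prf$y, prf$sigma1))
cat(sprintf("size-tuning optimum (centre radius): %.1f dva\n",
            set$center$outer_radius))
cat(sprintf("large annulus: [%.2f, %.2f] dva; medium: [%.2f, %.2f] dva\n",
            set$large$inner_radius, set$large$outer_radius,
            set$medium$inner_radius, set$medium$outer_radius))
cat(sprintf("pRF profile FWHM %.2f dva; zero crossing at %.2f dva\n",
            mk$fwhm_width,
            if (is.null(mk$zero_crossings)) NA else mk$zero_crossings[2]))

utils::write.table(
  data.frame(radius = set$size_tuning$radii,
             response = set$size_tuning$responses),
  file.path(out_dir, "size_tuning_curve.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

# raster of each stimulus at the working resolution, as plain text
for (kind in c("center", "medium", "large")) {
  img <- render_checkerboard(set[[kind]], prf, screen)
  utils::write.table(img, file.path(out_dir, paste0(kind, "_raster.tsv")),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}
cat("stimulus rasters and size-tuning curve written to", out_dir, "\n")
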