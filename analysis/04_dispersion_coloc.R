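#!/usr/bin/env Rscript
# Step 4: activity-triggered dispersion of a synaptic protein, and
# colocalization of the cargo with the synapse marker.

suppressPackageStartupMessages(library(dcvtrace))

out_root <- file.path("results", "dispersion_coloc")
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

## dispersion: 0.5 Hz / 180 s recordings, stim at 30 s ---------------------
at_report <- list()
for (seed in 1:4) {
  ds <- simulate_dispersion_scene(rng_seed = seed)
  dp <- dispersion_profiles(ds$movie, "protein", ds$synaptic_rois,
                            ds$extra_rois, ds$soma_roi, ds$protocol)
  write.csv(dp$group,
            file.path(out_root, sprintf("dispersion_cell%02d.csv", seed)),
            row.names = FALSE)
  ar <- dp$at_report
  ar$cell <- seed
  at_report[[seed]] <- ar
}
ar <- do.call(rbind, at_report)
write.csv(ar, file.path(out_root, "dispersion_at_160s.csv"),
          row.names = FALSE)
syn <- ar$dff_corr[ar$class == "synaptic"]
ext <- ar$dff_corr[ar$class == "extra-synaptic"]
cat(sprintf("dispersion at 160 s: synaptic %.3f +/- %.3f, shaft %+.3f +/- %.3f\n",
            mean(syn), sd(syn) / sqrt(length(syn)),
            mean(ext), sd(ext) / sqrt(length(ext))))
st <- compare_groups(syn, ext)
cat(sprintf("synaptic vs shaft: %s, p = %.3g\n", st$test, st$p_value))

## colocalization: cargo baseline vs synapse marker -------------------------
fx_dirs <- list.dirs(file.path("results", "fixtures"), recursive = FALSE)
fx_dirs <- fx_dirs[grepl("phluorin$", fx_dirs)]
if (!length(fx_dirs)) stop("no fixtures found; run analysis/01_simulate.R first")
coloc <- list()
for (d in fx_dirs) {
  fx <- read_fixture(d)
  # use the NH4+ epoch, when all cargo puncta are visible
  nh <- nh4_frames(fx$protocol)[1:3]
  cargo <- apply(fx$movie$channels$cargo[, , nh], c(1, 2), median)
  synm <- apply(fx$movie$channels$synapse[, , 1:4], c(1, 2), mean)
  mc <- manders_coefficients(cargo, synm)
  obj <- object_colocalization(detect_puncta(cargo), detect_puncta(synm),
                               radius_nm = 400)
  coloc[[basename(d)]] <- data.frame(
    cell_id = basename(d),
    pearson = pearson_coefficient(cargo, synm),
    manders_m1 = mc$m1, manders_m2 = mc$m2,
    object_frac_within_400nm = obj)
}
coloc_tab <- do.call(rbind, coloc)
write.csv(coloc_tab, file.path(out_root, "colocalization.csv"),
          row.names = FALSE)
cat(sprintf("colocalization (n = %d cells): Pearson %.2f, M1 %.2f, M2 %.2f, object %.2f\n",
            nrow(coloc_tab), mean(coloc_tab$pearson),
            mean(coloc_tab$manders_m1), mean(coloc_tab$manders_m2),
            mean(coloc_tab$object_frac_within_400nm)))
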