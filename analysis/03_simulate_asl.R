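#!/usr/bin/env Rscript
# Simulate the ASL bright image for the five sagittal slices at TI = 800 ms
# (HR 60) and tabulate per-slice totals, medians, COV and gradient.
library(pulmoasl)

net <- read_network("results/network")
sheet <- sheet_params(c_sheet = as.numeric(calibrate_sheet_conductance(net)))
sol <- solve_flow(net, sheet = sheet)
mr <- mr_params(ti = 800)

dir.create("results/images", showWarnings = FALSE, recursive = TRUE)
summary_rows <- list()
for (s in 1:5) {
  g <- simulate_asl_slice(net, sol, slice_plane(s), mr)
  write_voxel_csv(g, sprintf("results/images/slice%d_supine_co5.csv", s))
  lv <- lung_voxels(g)
  r <- asl_rate(lv)
  summary_rows[[s]] <- data.frame(
    slice = s, n_lung_voxels = nrow(lv),
    total_signal = sum(lv$total),
    capillary_share = sum(lv$capillary) / sum(lv$total),
    median_asl = median(r), mean_asl = mean(r), max_asl = max(r),
    cov = voxel_cov(g),
    gradient = gravitational_gradient(g))
}
tab <- do.call(rbind, summary_rows)
utils::write.csv(tab, "results/slice_summary.csv", row.names = FALSE)
print(tab, digits = 3)
cat("\nnote the lateral-to-medial rise in total signal and COV\n")
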