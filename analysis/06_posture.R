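#!/usr/bin/env Rscript
# Supine vs prone: per-slice COV and gravitational gradient with a paired
# two-sided t-test across the five slices.
library(pulmoasl)

net <- read_network("results/network")
sheet <- sheet_params(c_sheet = as.numeric(calibrate_sheet_conductance(net)))
rows <- data.frame(sv = 0.083, hr = 60, co = 5)
reports <- lapply(c("supine", "prone"), function(p)
  run_scenario(net, scenario_spec("posture", rows, posture = p, slices = 1:5),
               sheet = sheet))
names(reports) <- c("supine", "prone")

pc <- posture_comparison(reports$supine, reports$prone)
utils::write.csv(pc$table, "results/posture_pairs.csv", row.names = FALSE)
print(pc$table, digits = 3)
cat(sprintf("COV:      mean supine-prone difference %+0.3f, p = %s\n",
            pc$cov$mean_diff, format.pval(pc$cov$p_value, digits = 2)))
cat(sprintf("gradient: mean supine-prone difference %+0.4f, p = %s\n",
            pc$gradient$mean_diff, format.pval(pc$gradient$p_value, digits = 2)))
cat("single-network magnitudes are geometry-specific; the direction is the\n",
    "reproducible finding\n")
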