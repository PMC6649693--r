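#!/usr/bin/env Rscript
# Per-point CSP and intensity-ratio tracks for the simulated titration:
# the weighted CSP uses alpha_N = 0.14; intensity ratios are reported
# with a 3-residue averaging window, CSPs unsmoothed. Writes one TSV per
# track plus a profile figure for the highest ratio (1:2).

library(cspmap)

res <- run_analysis("results/sim/series.yaml", "results/run", plots = TRUE)

top <- length(res$csp)
csp <- res$csp[[top]]$data
cat(sprintf("titration points analysed: %s\n",
            paste(names(res$csp), collapse = ", ")))
cat(sprintf("at 1:2 the largest CSP is %.3f ppm at residue %d\n",
            max(csp$value, na.rm = TRUE),
            csp$residue_index[which.max(csp$value)]))
rat <- res$ratio[[top]]$data
cat(sprintf("%d residues are broadened beyond detection at 1:2\n",
            sum(rat$flag == "broadened_out")))
cat("tracks and run_report.yaml written under results/run/\n")
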