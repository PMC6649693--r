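#!/usr/bin/env Rscript
# Peak-trajectory linearity across the titration. Two-state fast
# exchange moves each peak along a straight free->bound line; a weak
# second site bends it. Classifies the reference dataset (single site:
# everything observed should be linear) and a two-site variant of the
# same construct, and summarises call rates.

library(cspmap)

sim <- generate_titration(sim_config(), seed = 42L)
calls <- classify_trajectories(sim$series, noise_sd = 0.003)
utils::write.table(calls, "results/trajectories_single_site.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("single-site reference dataset:\n")
print(table(calls$label))

seqc <- strsplit(sim_config()$sequence, "")[[1]]
amide <- which(seqc != "P")
cfg2 <- sim_config(
  patches = data.frame(start = 1L, end = length(seqc), dd_max = 0.2),
  model = binding_params(kd1 = 5, kd2 = 100, kex = 1e5),
  two_site = data.frame(residue = amide, ddh2 = -0.10, ddn2 = 0.11 / 0.14),
  helix_segment = NULL, strand_segment = NULL, noise_shift_sd = 0.001)
sim2 <- generate_titration(cfg2, seed = 42L)
calls2 <- classify_trajectories(sim2$series, noise_sd = 0.001)
utils::write.table(calls2, "results/trajectories_two_site.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
obs2 <- calls2[calls2$label %in% c("linear", "nonlinear"), ]
cat(sprintf("two-site variant (Kd2 = 20 x Kd1): %.1f%% of %d observed trajectories called nonlinear\n",
            100 * mean(obs2$label == "nonlinear"), nrow(obs2)))
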