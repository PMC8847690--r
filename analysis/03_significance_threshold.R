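#!/usr/bin/env Rscript
# Step 3 — experiment-wide significance.
#
# Estimates the correlation between the scans' multivariate statistics,
# draws replicate sets from the matching multivariate normal null, keeps
# each set's most extreme |Z|, and takes the 95th percentile as the
# experiment-wide threshold. The Bonferroni comparator for the same scan
# count is printed alongside. Set counts are scaled down from the
# study-scale defaults (10,000 sets of 1e6 draws) to desk scale.

library(pleioscan)

in_dir <- "results/synthetic"
out_dir <- "results"
seed <- 1L

scans <- list(
  read_sumstats(file.path(in_dir, "sumstats_PAD.tsv"), trait = "PAD",
                is_binary = TRUE, n_cases = 24009, n_controls = 150983),
  read_sumstats(file.path(in_dir, "sumstats_CAD.tsv"), trait = "CAD",
                is_binary = TRUE, n_cases = 122733, n_controls = 424528),
  read_sumstats(file.path(in_dir, "sumstats_LDL.tsv"), trait = "LDL",
                n_total = 723000))
panel <- harmonize_panel(scans)
R <- suppressWarnings(estimate_z_correlation(panel))
defs <- enumerate_scans(c("PAD", "CAD"), "LDL")
results <- lapply(defs, function(d) scan_panel(panel, d, R))
Rs <- scan_correlation(results)
cat("scan-level correlation:\n")
print(round(Rs$matrix, 3))

th <- resampling_threshold(Rs, set_size = nrow(panel$index),
                           n_sets = 2000, percentile = 0.95, seed = seed)
print(th)
bon <- bonferroni_threshold(5e-8, length(defs))
cat(sprintf("Bonferroni comparator over %d scans: %.3g (z = %.3f)\n",
            length(defs), bon, p_to_z(bon)))
cat(sprintf("resampled threshold is %s stringent than Bonferroni\n",
            ifelse(th$p_star > bon, "less", "more")))

out <- data.frame(z_star = th$z_star, p_star = th$p_star,
                  percentile = th$percentile, n_sets = th$n_sets,
                  set_size = th$set_size, seed = th$seed,
                  bonferroni_p = bon)
write.table(format(out, digits = 6), file.path(out_dir, "threshold.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
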