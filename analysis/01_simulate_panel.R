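#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study.
#
# Builds a compact multi-trait summary-statistics panel with the structure
# the analysis assumes: two case-control atherosclerosis traits (PAD, CAD)
# and one quantitative risk factor (LDL); AR(1) LD blocks; cross-trait
# null correlation 0.3 from sample overlap; three planted shared
# (pleiotropic) loci, one trait-specific locus, and one shared locus
# recorded in the known-association catalog. Files are written in the
# dialects the downstream steps consume.

library(pleioscan)

out_dir <- "results/synthetic"
seed <- 1L

cfg <- sim_config(
  traits = c("PAD", "CAD", "LDL"),
  is_binary = c(TRUE, TRUE, FALSE),
  n_per_trait = c(round(effective_sample_size(24009, 150983)),
                  round(effective_sample_size(122733, 424528)),
                  723000),
  n_blocks = 40, block_size = 25, within_block_rho = 0.8,
  cross_trait_null_corr = 0.3,
  planted_loci = list(
    list(block = 5, traits = c("PAD", "CAD"), ncp = 5.5, shared = TRUE),
    list(block = 14, traits = c("PAD", "CAD", "LDL"), ncp = 5,
         shared = TRUE),
    list(block = 23, traits = c("PAD", "LDL"), ncp = 5.5, shared = TRUE),
    list(block = 31, traits = "PAD", ncp = 7),
    list(block = 37, traits = c("PAD", "CAD"), ncp = 5.5, shared = TRUE,
         known = TRUE)),
  seed = seed)

pan <- simulate_panel(cfg, dir = out_dir)
print(pan)
cat("planted loci:\n")
print(pan$truth)

qtl <- simulate_molecular_qtl(pan, 1, colocalized = TRUE, gene = "GENEA",
                              tissue = "artery", seed = seed)
qtl2 <- simulate_molecular_qtl(pan, 2, colocalized = FALSE,
                               gene = "GENEB", tissue = "liver",
                               seed = seed + 1)
qtab <- rbind(qtl$table, qtl2$table)
write.table(qtab, file.path(out_dir, "qtl_pairs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(rbind(qtl$truth, qtl2$truth),
            file.path(out_dir, "qtl_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote", length(list.files(out_dir)), "files under", out_dir, "\n")
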