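# In-code fixtures shared across test files.

write_tiny_sumstats <- function(path, rows) {
  df <- do.call(rbind, lapply(rows, as.data.frame))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# a 5-variant well-formed summary-statistics file in the default dialect
tiny_sumstats_file <- function(path = tempfile(fileext = ".tsv")) {
  write_tiny_sumstats(path, list(
    list(SNP = "rs1", CHR = "1", BP = 1000, A1 = "A", A2 = "G",
         freq = 0.2, b = 0.10, se = 0.05, p = z_to_p(2), N = 50000),
    list(SNP = "rs2", CHR = "1", BP = 2000, A1 = "C", A2 = "T",
         freq = 0.4, b = -0.05, se = 0.05, p = z_to_p(1), N = 50000),
    list(SNP = "rs1531817", CHR = "15", BP = 101906737, A1 = "C",
         A2 = "A", freq = 0.68, b = 0.035, se = 0.01,
         p = z_to_p(3.5), N = 41430),
    list(SNP = "rs4", CHR = "2", BP = 5000, A1 = "G", A2 = "T",
         freq = 0.1, b = 0.02, se = 0.04, p = z_to_p(0.5), N = 50000),
    list(SNP = "rs5", CHR = "2", BP = 9000, A1 = "A", A2 = "C",
         freq = 0.3, b = 0.00, se = 0.02, p = 1, N = 50000)
  ))
}

# deterministic two-trait scans over the same variants, trait B with
# swapped alleles at rs2 (sign flip expected) and an ambiguous A/T variant
make_scan <- function(trait, ids, chrom, pos, a1, a2, z, n = 10000,
                      is_binary = FALSE) {
  se <- rep(0.02, length(ids))
  v <- data.frame(variant_id = ids, chrom = chrom, pos = pos,
                  effect_allele = a1, other_allele = a2, eaf = 0.3,
                  beta = z * se, se = se, z = z, p = z_to_p(z), n = n,
                  stringsAsFactors = FALSE)
  structure(list(trait = trait, is_binary = is_binary,
                 n_total = n, variants = v, n_rejected = 0L),
            class = "trait_scan")
}

# standard assoc window for coloc tests: given z-scores on a typical GWAS
# effect scale (se = 0.03, beta = z * se)
make_assoc <- function(z, label = "t", pos = NULL, se = 0.03,
                       kind = "quantitative") {
  n <- length(z)
  assoc_vector(sprintf("v%03d", seq_len(n)), beta = z * se,
               se = rep(se, n), pos = pos %||% (seq_len(n) * 1000L),
               label = label, trait_kind = kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
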