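# Published reference table of atherosclerosis multi-trait sentinel SNPs
# and the nine-trait scan inventory, used as printed-number inputs for
# consistency checks of the filter and merging rules.

#' Published atherosclerosis multi-trait sentinel loci
#'
#' The 31 sentinel SNPs reported by a published multi-trait (N-GWAMA)
#' analysis of peripheral and coronary artery disease with seven
#' cardiometabolic risk factors: scan traits, sentinel variant, GRCh37
#' position, alleles, per-trait direction of effect, effect-allele
#' frequency, multivariate p-value and per-trait single p-values
#' (`p_trait3` is `NA` for bivariate scans).
#'
#' @return data frame with 31 rows.
#' @examples
#' nrow(reference_sentinels())
#' @export
reference_sentinels <- function() {
  path <- system.file("extdata", "atherosclerosis_multitrait_loci.tsv",
                      package = "pleioscan", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character"))
  tab
}

#' The nine-trait scan inventory
#'
#' Trait labels, case-control flags and study sample sizes of the nine
#' atherosclerosis and risk-factor GWAS behind the reference scan design:
#' PAD (24,009 cases / 150,983 controls), CAD (122,733 / 424,528), T2D
#' (228,499 / 1,178,783), BMI (806,834), smoking initiation (462,690) and
#' the four lipid traits LDL, HDL, TC, TG (723,000 each). Binary traits
#' carry their effective sample size `4/(1/cases + 1/controls)`.
#'
#' @return data frame with columns `trait`, `is_binary`, `n_cases`,
#'   `n_controls`, `n_total`, `n_eff`.
#' @export
trait_inventory <- function() {
  inv <- data.frame(
    trait = c("PAD", "CAD", "T2D", "BMI", "SMK", "LDL", "HDL", "TC", "TG"),
    is_binary = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                  FALSE),
    n_cases = c(24009, 122733, 228499, NA, NA, NA, NA, NA, NA),
    n_controls = c(150983, 424528, 1178783, NA, NA, NA, NA, NA, NA),
    n_total = c(NA, NA, NA, 806834, 462690, 723000, 723000, 723000,
                723000),
    stringsAsFactors = FALSE
  )
  inv$n_eff <- inv$n_total
  bin <- inv$is_binary
  inv$n_eff[bin] <- mapply(effective_sample_size, inv$n_cases[bin],
                           inv$n_controls[bin])
  inv
}
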