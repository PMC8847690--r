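# Reading, validating and harmonizing GWAS summary statistics, pairwise LD
# tables and known-association catalogs.

#' Default summary-statistics column dialect
#'
#' Column-name mapping used by [read_sumstats()]. The defaults follow the
#' GCTA-COJO `.ma` dialect (`SNP A1 A2 freq b se p N`) extended with the
#' chromosome/position columns (`CHR`, `BP`) that locus definition needs.
#' Override individual entries to read other layouts, e.g.
#' `ma_dialect(id = "rsid", pos = "position")`. Entries may be set to `NA`
#' to declare a column absent.
#'
#' @param id,chrom,pos,effect_allele,other_allele,eaf,beta,se,z,p,n column
#'   names in the file for each field.
#' @return Named character vector mapping field names to file columns.
#' @export
ma_dialect <- function(id = "SNP", chrom = "CHR", pos = "BP",
                       effect_allele = "A1", other_allele = "A2",
                       eaf = "freq", beta = "b", se = "se", z = "Z",
                       p = "p", n = "N") {
  c(id = id, chrom = chrom, pos = pos, effect_allele = effect_allele,
    other_allele = other_allele, eaf = eaf, beta = beta, se = se, z = z,
    p = p, n = n)
}

#' Effective sample size for a case-control GWAS
#'
#' `4 / (1/N_cases + 1/N_controls)`, the standard effective N used to weight
#' case-control studies in sample-size-weighted meta-analysis.
#'
#' @param n_cases,n_controls positive case and control counts.
#' @return Effective sample size (numeric).
#' @examples
#' effective_sample_size(24009, 150983)
#' @export
effective_sample_size <- function(n_cases, n_controls) {
  stopifnot(n_cases > 0, n_controls > 0)
  4 / (1 / n_cases + 1 / n_controls)
}

#' Read one trait's GWAS summary statistics
#'
#' Reads a tab-delimited summary-statistics file into a `trait_scan`,
#' filling `z` from `beta/se` when absent and `p` from the two-sided normal
#' tail of `z` when absent. Rows with non-positive standard errors, missing
#' alleles or non-positive positions are rejected and counted in the parse
#' report. When `p` and `z` are both present but inconsistent beyond a
#' relative tolerance of 1e-3, `z` wins and a warning is issued.
#'
#' @param path file path.
#' @param trait trait label.
#' @param dialect column mapping, see [ma_dialect()].
#' @param is_binary is the trait case-control?
#' @param n_cases,n_controls case/control counts for binary traits; used to
#'   compute the effective sample size when the file has no `n` column.
#' @param n_total per-study sample size used when the file has no `n`
#'   column (quantitative traits).
#' @return A `trait_scan`: list with `trait`, `is_binary`, `n_total`,
#'   `variants` (data frame sorted by chromosome and position) and
#'   `n_rejected`.
#' @export
read_sumstats <- function(path, trait, dialect = ma_dialect(),
                          is_binary = FALSE, n_cases = NULL,
                          n_controls = NULL, n_total = NULL) {
  stopifnot(file.exists(path))
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("id", "chrom", "pos", "effect_allele", "other_allele")
  for (f in need) {
    if (is.na(dialect[[f]]) || !dialect[[f]] %in% names(raw)) {
      stop("mandatory column '", dialect[[f]], "' (", f, ") missing in ",
           path, call. = FALSE)
    }
  }
  get_col <- function(f) {
    cn <- dialect[[f]]
    if (!is.na(cn) && cn %in% names(raw)) raw[[cn]] else NULL
  }
  v <- data.frame(
    variant_id    = as.character(get_col("id")),
    chrom         = as.character(get_col("chrom")),
    pos           = as.integer(get_col("pos")),
    effect_allele = toupper(as.character(get_col("effect_allele"))),
    other_allele  = toupper(as.character(get_col("other_allele"))),
    stringsAsFactors = FALSE
  )
  v$eaf  <- if (!is.null(get_col("eaf"))) as.numeric(get_col("eaf")) else NA_real_
  v$beta <- if (!is.null(get_col("beta"))) as.numeric(get_col("beta")) else NA_real_
  v$se   <- if (!is.null(get_col("se"))) as.numeric(get_col("se")) else NA_real_
  v$z    <- if (!is.null(get_col("z"))) as.numeric(get_col("z")) else NA_real_
  v$p    <- if (!is.null(get_col("p"))) as.numeric(get_col("p")) else NA_real_
  v$n    <- if (!is.null(get_col("n"))) as.numeric(get_col("n")) else NA_real_

  if (all(is.na(v$z)) && (all(is.na(v$beta)) || all(is.na(v$se)))) {
    stop("need either a z column or beta+se columns in ", path, call. = FALSE)
  }

  bad <- rep(FALSE, nrow(v))
  bad <- bad | is.na(v$pos) | v$pos <= 0
  bad <- bad | is.na(v$effect_allele) | is.na(v$other_allele) |
    v$effect_allele == "" | v$other_allele == ""
  # zero/negative SE invalidates the row unless z was given directly
  bad <- bad | (is.na(v$z) & (is.na(v$se) | v$se <= 0))
  bad <- bad | (!is.na(v$se) & v$se <= 0)
  n_rejected <- sum(bad)
  v <- v[!bad, , drop = FALSE]

  fill <- is.na(v$z) & !is.na(v$beta) & !is.na(v$se)
  v$z[fill] <- v$beta[fill] / v$se[fill]

  p_from_z <- z_to_p(v$z)
  both <- !is.na(v$p) & !is.na(v$z) & v$p > 0
  incons <- both & abs(v$p - p_from_z) / p_from_z > 1e-3
  if (any(incons)) {
    warning(sum(incons), " rows with p inconsistent with z in '", trait,
            "'; z wins", call. = FALSE)
  }
  v$p[is.na(v$p) | incons] <- p_from_z[is.na(v$p) | incons]

  if (any(is.na(v$n))) {
    n_study <- if (is_binary && !is.null(n_cases)) {
      effective_sample_size(n_cases, n_controls)
    } else {
      n_total
    }
    if (is.null(n_study) && all(is.na(v$n))) {
      stop("no sample size available for trait '", trait,
           "': supply an n column, n_total, or case/control counts",
           call. = FALSE)
    }
    if (!is.null(n_study)) v$n[is.na(v$n)] <- n_study
  }

  v <- v[order(v$chrom, v$pos, v$variant_id), , drop = FALSE]
  rownames(v) <- NULL
  n_tot <- n_total %||%
    (if (is_binary && !is.null(n_cases)) effective_sample_size(n_cases, n_controls)
     else stats::median(v$n))
  structure(
    list(trait = trait, is_binary = is_binary, n_total = n_tot,
         variants = v, n_rejected = n_rejected),
    class = "trait_scan"
  )
}

#' Write a trait scan back to disk
#'
#' Inverse of [read_sumstats()]: emits a tab-delimited table under the given
#' dialect. Round-trips all mapped fields at full precision.
#'
#' @param scan a `trait_scan`.
#' @param path output file.
#' @param dialect column mapping, see [ma_dialect()].
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(scan, path, dialect = ma_dialect()) {
  v <- scan$variants
  out <- data.frame(v$variant_id, v$chrom, v$pos, v$effect_allele,
                    v$other_allele, v$eaf, v$beta, v$se, v$z, v$p, v$n,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- unname(dialect[c("id", "chrom", "pos", "effect_allele",
                                 "other_allele", "eaf", "beta", "se", "z",
                                 "p", "n")])
  utils::write.table(format(out, digits = 17, scientific = NA, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align several trait scans onto a shared variant index
#'
#' Intersects the variant sets of two or more scans (keyed by chromosome,
#' position and unordered allele pair), orients every trait's z-score to the
#' first scan's effect allele (flipping signs where the effect/other alleles
#' are swapped), drops strand-ambiguous variants (A/T, C/G) and variants
#' whose allele pairs disagree across scans.
#'
#' @param scans list of `trait_scan` objects (>= 2).
#' @return A `harmonized_panel`: list with `traits`, `index` (data frame of
#'   key/chrom/pos/alleles/eaf), and variants-by-traits matrices `z_matrix`,
#'   `n_matrix`, `p_matrix`, plus `n_dropped` bookkeeping.
#' @export
harmonize_panel <- function(scans) {
  stopifnot(length(scans) >= 2)
  traits <- vapply(scans, function(s) s$trait, character(1))
  if (anyDuplicated(traits)) stop("duplicate trait labels", call. = FALSE)

  keyed <- lapply(scans, function(s) {
    v <- s$variants
    v$key <- variant_key(v$chrom, v$pos, v$effect_allele, v$other_allele)
    amb <- is_strand_ambiguous(v$effect_allele, v$other_allele)
    v <- v[!amb & !duplicated(v$key), , drop = FALSE]
    v
  })
  n_ambiguous <- sum(vapply(seq_along(scans), function(i) {
    nrow(scans[[i]]$variants) - nrow(keyed[[i]])
  }, numeric(1)))

  keys <- Reduce(intersect, lapply(keyed, function(v) v$key))
  if (!length(keys)) {
    sizes <- utils::combn(seq_along(keyed), 2, function(ij) {
      length(intersect(keyed[[ij[1]]]$key, keyed[[ij[2]]]$key))
    })
    pairs <- utils::combn(traits, 2)
    worst <- which.min(sizes)
    stop("no overlapping variants; most disjoint scans: ",
         pairs[1, worst], " vs ", pairs[2, worst], call. = FALSE)
  }

  ref <- keyed[[1]][match(keys, keyed[[1]]$key), , drop = FALSE]
  K <- length(scans)
  z <- n <- p <- matrix(NA_real_, length(keys), K,
                        dimnames = list(keys, traits))
  mismatched <- rep(FALSE, length(keys))
  for (k in seq_len(K)) {
    v <- keyed[[k]][match(keys, keyed[[k]]$key), , drop = FALSE]
    same <- v$effect_allele == ref$effect_allele &
      v$other_allele == ref$other_allele
    flip <- v$effect_allele == ref$other_allele &
      v$other_allele == ref$effect_allele
    mismatched <- mismatched | (!same & !flip)
    zz <- v$z
    zz[flip] <- -zz[flip]
    z[, k] <- zz
    n[, k] <- v$n
    p[, k] <- v$p
  }
  keep <- !mismatched & stats::complete.cases(z)
  index <- data.frame(key = keys, chrom = ref$chrom, pos = ref$pos,
                      effect_allele = ref$effect_allele,
                      other_allele = ref$other_allele,
                      variant_id = ref$variant_id, eaf = ref$eaf,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  ord <- order(index$chrom, index$pos, index$key)
  index <- index[ord, , drop = FALSE]
  rownames(index) <- NULL
  pick <- which(keep)[ord]
  structure(
    list(traits = traits, index = index,
         z_matrix = z[pick, , drop = FALSE],
         n_matrix = n[pick, , drop = FALSE],
         p_matrix = p[pick, , drop = FALSE],
         n_dropped = list(strand_ambiguous = n_ambiguous,
                          allele_mismatch = sum(mismatched))),
    class = "harmonized_panel"
  )
}

#' Read a pairwise LD table
#'
#' Accepts either the minimal 3-column dialect (`id1 id2 r2`) or a
#' PLINK-style pairwise table (`CHR_A BP_A SNP_A CHR_B BP_B SNP_B R2`); an
#' optional signed `R` column is kept for conditional analysis. Lookups are
#' symmetric; absent pairs return `default_r2`.
#'
#' @param path file path.
#' @param default_r2 value returned for pairs absent from the table.
#' @return An `ld_table`.
#' @export
read_ld_table <- function(path, default_r2 = 0) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  nm <- toupper(names(tab))
  if (all(c("SNP_A", "SNP_B", "R2") %in% nm)) {
    id1 <- tab[[which(nm == "SNP_A")]]
    id2 <- tab[[which(nm == "SNP_B")]]
    r2 <- as.numeric(tab[[which(nm == "R2")]])
    r <- if ("R" %in% nm) as.numeric(tab[[which(nm == "R")]]) else NULL
  } else if (ncol(tab) >= 3) {
    id1 <- as.character(tab[[1]]); id2 <- as.character(tab[[2]])
    r2 <- as.numeric(tab[[3]])
    r <- if (ncol(tab) >= 4) as.numeric(tab[[4]]) else NULL
  } else {
    stop("unrecognized LD table layout in ", path, call. = FALSE)
  }
  bad <- which(is.na(r2) | r2 < 0 | r2 > 1)
  if (length(bad)) {
    stop("r2 outside [0,1] at row ", bad[1], " of ", path, call. = FALSE)
  }
  ld_table(id1, id2, r2, r, default_r2 = default_r2)
}

#' Build an LD table from vectors
#'
#' @param id1,id2 variant ids of each pair.
#' @param r2 squared correlation in `[0,1]`.
#' @param r optional signed correlation.
#' @param default_r2 value returned for absent pairs.
#' @return An `ld_table`.
#' @export
ld_table <- function(id1, id2, r2, r = NULL, default_r2 = 0) {
  stopifnot(length(id1) == length(id2), length(id2) == length(r2))
  key <- paste(pmin(id1, id2), pmax(id1, id2), sep = "\r")
  r2v <- stats::setNames(r2, key)
  rv <- if (!is.null(r)) stats::setNames(r, key) else NULL
  structure(list(r2 = r2v, r = rv, default_r2 = default_r2),
            class = "ld_table")
}

#' Query squared LD between two variants
#'
#' @param ld an `ld_table`.
#' @param a,b variant ids (vectorized).
#' @return r-squared values; `1` when `a == b`, the table default when the
#'   pair is absent.
#' @export
ld_r2 <- function(ld, a, b) {
  out <- ifelse(a == b, 1, ld$r2[paste(pmin(a, b), pmax(a, b), sep = "\r")])
  out[is.na(out)] <- ld$default_r2
  unname(out)
}

#' Query signed LD correlation between two variants
#'
#' Falls back to `+sqrt(r2)` (with a warning, once) when the table carries
#' no signed column.
#'
#' @inheritParams ld_r2
#' @return signed r values.
#' @export
ld_r <- function(ld, a, b) {
  if (is.null(ld$r)) {
    warning("LD table has no signed r column; using +sqrt(r2)",
            call. = FALSE)
    return(sqrt(ld_r2(ld, a, b)))
  }
  out <- ifelse(a == b, 1, ld$r[paste(pmin(a, b), pmax(a, b), sep = "\r")])
  out[is.na(out)] <- 0
  unname(out)
}

#' Read a known-association catalog
#'
#' Tab-delimited table with columns `trait`, `rsid` (or `variant_id`),
#' `chrom`, `pos`. Rows without a mappable position are dropped and
#' counted. Trait labels are preserved verbatim for exact-string matching
#' against scan traits.
#'
#' @param path file path.
#' @return data frame of known associations with attribute `n_dropped`.
#' @export
read_catalog <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  nm <- tolower(names(tab))
  names(tab) <- nm
  idcol <- intersect(c("rsid", "variant_id", "variant", "snp"), nm)[1]
  stopifnot(all(c("trait", "chrom", "pos") %in% nm), !is.na(idcol))
  out <- data.frame(trait = as.character(tab$trait),
                    variant_id = as.character(tab[[idcol]]),
                    chrom = as.character(tab$chrom),
                    pos = suppressWarnings(as.integer(tab$pos)),
                    stringsAsFactors = FALSE)
  drop <- is.na(out$pos) | out$pos <= 0
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' @export
print.trait_scan <- function(x, ...) {
  cat("<trait_scan> ", x$trait, if (x$is_binary) " (binary)" else "",
      ": ", nrow(x$variants), " variants, N = ", round(x$n_total),
      ", rejected rows: ", x$n_rejected, "\n", sep = "")
  invisible(x)
}

#' @export
print.harmonized_panel <- function(x, ...) {
  cat("<harmonized_panel> ", length(x$traits), " traits (",
      paste(x$traits, collapse = ", "), "), ", nrow(x$index),
      " shared variants\n", sep = "")
  invisible(x)
}
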