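# End-to-end cascade: harmonize -> enumerate scans -> N-GWAMA -> empirical
# threshold -> sentinels/loci -> pleiotropy & novelty filters -> trait-trait
# colocalization (with conditional-analysis rescue) -> merge -> QTL
# colocalization -> Table-shaped report.

#' Pipeline configuration
#'
#' Collects every constant of the cascade. Defaults follow the standard
#' design: nominal single-trait association `5e-3`, single-trait
#' genome-wide `5e-8`, multivariate genome-wide `5e-8`, 95th-percentile
#' resampling threshold, 1 Mb locus window, 500 kb colocalization and
#' novelty windows, LD cutoffs `r2 > 0.2` (locus/novelty) and `r2 < 0.1`
#' (secondary signal).
#'
#' @param core character pair of core disease traits.
#' @param risk character vector of risk-factor traits.
#' @param nominal_p,gw_p,alpha_gw filter thresholds.
#' @param percentile,n_sets,set_size resampling-threshold parameters;
#'   `set_size = NULL` uses the panel's variant count.
#' @param locus_window_bp,coloc_window_bp,novelty_window_bp windows in bp.
#' @param r2_locus,r2_secondary LD cutoffs.
#' @param priors colocalization priors, see [coloc_priors()].
#' @param coloc_keep minimum conditional colocalization probability for a
#'   locus to be kept (default 0.8).
#' @param hla HLA exclusion region.
#' @param seed integer seed for the resampling threshold.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(core, risk = character(),
                            nominal_p = 5e-3, gw_p = 5e-8,
                            alpha_gw = 5e-8, percentile = 0.95,
                            n_sets = 1000, set_size = NULL,
                            locus_window_bp = 1e6, coloc_window_bp = 5e5,
                            novelty_window_bp = 5e5, r2_locus = 0.2,
                            r2_secondary = 0.1, priors = coloc_priors(),
                            coloc_keep = 0.8, hla = hla_region_grch37(),
                            seed = 1L) {
  stopifnot(length(core) == 2, nominal_p > 0, nominal_p < 1,
            gw_p > 0, gw_p < 1, percentile > 0, percentile < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

# Rebuild GWAS-scale effects from the panel: se = 1/sqrt(2 n maf (1-maf)),
# beta = z * se. The Wakefield prior SDs (0.15 / 0.2) are calibrated for
# the trait scale, so colocalization must not run on bare unit-variance z.
#' @noRd
assoc_from_panel <- function(panel, trait, is_binary = FALSE) {
  maf <- panel$index$eaf
  maf[!is.finite(maf)] <- 0.25
  maf <- pmin(pmax(maf, 0.01), 0.99)
  se <- 1 / sqrt(2 * panel$n_matrix[, trait] * maf * (1 - maf))
  z <- panel$z_matrix[, trait]
  assoc_vector(panel$index$variant_id, beta = z * se, se = se,
               pos = panel$index$pos, label = trait,
               trait_kind = if (is_binary) "case_control" else "quantitative")
}

#' Run the full discovery cascade
#'
#' Executes the whole pipeline over harmonized in-memory scans: N-GWAMA
#' for every scan in the design, the empirical experiment-wide threshold
#' from the scan-level correlation, greedy sentinel/locus discovery,
#' pleiotropy/HLA/novelty filters, trait-trait colocalization (pairwise or
#' trivariate by scan size; borderline loci retried after approximate
#' conditional analysis), cross-scan locus merging with tier assignment,
#' and optional molecular-QTL colocalization. Deterministic given
#' `config$seed`.
#'
#' @param scans list of `trait_scan` objects covering the design's traits.
#' @param config a [pipeline_config()].
#' @param ld an `ld_table` or `NULL`.
#' @param catalog known-association data frame (may be empty).
#' @param qtl optional significant-pair QTL data frame.
#' @return a `run_report`: list with `loci` (per-locus data frame),
#'   `clusters`, `stage_counts`, `threshold`, `scan_corr`, `qtl`,
#'   `manifest`.
#' @export
run_pipeline <- function(scans, config, ld = NULL,
                         catalog = NULL, qtl = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(catalog)) {
    catalog <- data.frame(trait = character(), variant_id = character(),
                          chrom = character(), pos = integer(),
                          stringsAsFactors = FALSE)
  }
  traits <- vapply(scans, function(s) s$trait, character(1))
  binary <- vapply(scans, function(s) isTRUE(s$is_binary), logical(1))
  panel <- harmonize_panel(scans)
  defs <- enumerate_scans(config$core, config$risk)
  R_traits <- suppressWarnings(estimate_z_correlation(panel))
  results <- lapply(defs, function(d) scan_panel(panel, d, R_traits))
  R_scans <- if (length(results) >= 2) {
    scan_correlation(results)
  } else {
    structure(list(traits = defs[[1]]$label,
                   matrix = matrix(1, 1, 1,
                                   dimnames = list(defs[[1]]$label,
                                                   defs[[1]]$label))),
              class = "cross_trait_corr")
  }
  M <- config$set_size %||% nrow(panel$index)
  threshold <- resampling_threshold(R_scans, set_size = M,
                                    n_sets = config$n_sets,
                                    percentile = config$percentile,
                                    seed = config$seed)

  stage_counts <- list()
  kept <- list()
  for (si in seq_along(results)) {
    res <- results[[si]]
    def <- defs[[si]]
    sentinels <- find_sentinels(res, config$gw_p, ld,
                                config$locus_window_bp, config$r2_locus)
    loci <- lapply(sentinels, define_locus, result = res, ld = ld,
                   window_bp = config$locus_window_bp,
                   r2_min = config$r2_locus)
    n0 <- length(loci)
    loci <- lapply(loci, apply_pleiotropy_filters,
                   nominal_p = config$nominal_p, gw_p = config$gw_p,
                   hla = config$hla)
    loci_hla <- Filter(function(l) l$verdicts$outside_hla, loci)
    loci_pleio <- Filter(function(l) l$verdicts$pleiotropy_pass, loci_hla)
    loci_ngw <- Filter(function(l) l$verdicts$not_gw_single, loci_pleio)
    loci_nov <- lapply(loci_ngw, apply_novelty_filter, catalog = catalog,
                       result = res, ld = ld,
                       proximity_bp = config$novelty_window_bp,
                       r2_min = config$r2_locus)
    loci_nov <- Filter(function(l) l$verdicts$novel_vs_catalog, loci_nov)

    coloc_pass <- list()
    for (l in loci_nov) {
      cres <- trait_trait_coloc(l, panel, traits, binary, config, ld)
      l$coloc <- cres
      ok <- !is.na(cres$conditional_prob) &&
        cres$conditional_prob >= config$coloc_keep
      l$verdicts$coloc_pass <- ok
      if (ok || identical(cres$verdict, "borderline")) {
        coloc_pass <- c(coloc_pass, list(l))
      }
    }
    keep_strict <- Filter(function(l) l$verdicts$coloc_pass, coloc_pass)
    stage_counts[[def$label]] <- data.frame(
      scan = def$label, n_variants = nrow(res),
      significant_sentinels = n0, outside_hla = length(loci_hla),
      pleiotropy = length(loci_pleio), not_gw_single = length(loci_ngw),
      novel = length(loci_nov), colocalized = length(keep_strict),
      stringsAsFactors = FALSE)
    kept <- c(kept, coloc_pass)
  }
  stage_counts <- do.call(rbind, unname(stage_counts))
  rownames(stage_counts) <- NULL

  for (i in seq_along(kept)) {
    kept[[i]]$tier <-
      if (kept[[i]]$sentinel$p_multi < threshold$p_star) {
        "experiment_wide"
      } else if (kept[[i]]$sentinel$p_multi < config$alpha_gw) {
        "nominal"
      } else {
        "none"
      }
  }
  loci_df <- report_loci_table(kept)
  clusters <- if (length(kept)) {
    merge_independent_loci(kept, config$locus_window_bp)
  } else {
    list(cluster = integer(), representatives = integer(), n_clusters = 0)
  }

  qtl_res <- NULL
  if (!is.null(qtl) && length(kept)) {
    qtl_res <- list()
    for (ri in clusters$representatives) {
      l <- kept[[ri]]
      core_p <- vapply(config$core, function(t) {
        pc <- paste0("p.", t)
        if (pc %in% names(l$sentinel)) l$sentinel[[pc]] else NA_real_
      }, numeric(1))
      lead <- config$core[which.min(core_p)]
      gwas <- assoc_from_panel(panel, lead, binary[match(lead, traits)])
      tab <- qtl_colocalize(gwas, qtl, l$sentinel$variant_id,
                            l$sentinel$pos, config$priors,
                            config$coloc_window_bp, ld)
      if (nrow(tab)) {
        tab <- cbind(data.frame(locus = l$sentinel$variant_id,
                                stringsAsFactors = FALSE), tab)
        qtl_res[[length(qtl_res) + 1]] <- tab
      }
    }
    qtl_res <- if (length(qtl_res)) do.call(rbind, qtl_res) else NULL
  }

  structure(
    list(loci = loci_df, loci_objects = kept, clusters = clusters,
         stage_counts = stage_counts, threshold = threshold,
         scan_corr = R_scans, qtl = qtl_res,
         manifest = list(
           package_version = as.character(utils::packageVersion("pleioscan")),
           seed = config$seed, n_scans = length(defs),
           traits = traits,
           nominal_p = config$nominal_p, gw_p = config$gw_p,
           alpha_gw = config$alpha_gw,
           bonferroni_p = bonferroni_threshold(config$alpha_gw,
                                               length(defs)),
           z_star = threshold$z_star, p_star = threshold$p_star)),
    class = "run_report")
}

# trait-trait colocalization for one locus, with the borderline ->
# conditional-analysis rescue path.
#' @noRd
trait_trait_coloc <- function(locus, panel, traits, binary, config, ld) {
  st <- locus$scan$traits
  vecs <- lapply(st, function(t) {
    assoc_from_panel(panel, t, binary[match(t, traits)])
  })
  run1 <- function(vlist) {
    if (length(vlist) == 2) {
      coloc_pairwise(vlist[[1]], vlist[[2]], config$priors,
                     locus$sentinel$pos, config$coloc_window_bp)
    } else {
      moloc_trivariate(vlist[[1]], vlist[[2]], vlist[[3]], config$priors,
                       locus$sentinel$pos, config$coloc_window_bp)
    }
  }
  res <- run1(vecs)
  if (identical(res$verdict, "borderline") && !is.null(ld)) {
    half <- config$coloc_window_bp / 2
    for (ti in seq_along(vecs)) {
      w <- vecs[[ti]][abs(vecs[[ti]]$pos - locus$sentinel$pos) <= half, ]
      sec <- detect_secondary_signal(w, locus$sentinel$variant_id, ld,
                                     r2_max = config$r2_secondary)
      if (!is.null(sec)) {
        vecs2 <- vecs
        vecs2[[ti]] <- condition_assoc(vecs[[ti]], sec, ld)
        res2 <- run1(vecs2)
        res2$conditioned_on <- sec
        if (!is.na(res2$conditional_prob) &&
            res2$conditional_prob > res$conditional_prob %||% 0) {
          res <- res2
        }
        break
      }
    }
  }
  res
}

#' @noRd
report_loci_table <- function(kept) {
  if (!length(kept)) {
    return(data.frame(scan = character(), sentinel = character(),
                      chrom = character(), pos = integer(),
                      effect_allele = character(),
                      other_allele = character(), direction = character(),
                      eaf = numeric(), p_multi = numeric(),
                      p_traits = character(), tier = character(),
                      coloc_prob = numeric(), coloc_verdict = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(kept, function(l) {
    s <- l$sentinel
    pt <- paste(vapply(l$scan$traits, function(t) {
      format(s[[paste0("p.", t)]], digits = 3)
    }, character(1)), collapse = ";")
    data.frame(scan = l$scan$label, sentinel = s$variant_id,
               chrom = s$chrom, pos = s$pos,
               effect_allele = s$effect_allele,
               other_allele = s$other_allele, direction = s$direction,
               eaf = s$eaf, p_multi = s$p_multi, p_traits = pt,
               tier = l$tier,
               coloc_prob = l$coloc$conditional_prob %||% NA_real_,
               coloc_verdict = l$coloc$verdict %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
}

#' Write a run report to disk
#'
#' Emits the Table-shaped locus TSV, the per-scan stage-count TSV, the QTL
#' colocalization TSV (when present) and a YAML reproducibility manifest.
#' Byte-identical across repeated calls on the same report.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    df2 <- df
    for (j in seq_along(df2)) {
      if (is.numeric(df2[[j]]) && !is.integer(df2[[j]])) {
        df2[[j]] <- formatC(df2[[j]], digits = 6, format = "g")
      }
    }
    df2
  }
  paths <- list(loci = file.path(dir, "loci.tsv"),
                stage_counts = file.path(dir, "stage_counts.tsv"),
                manifest = file.path(dir, "manifest.yaml"))
  utils::write.table(fmt(report$loci), paths$loci, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fmt(report$stage_counts), paths$stage_counts,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$qtl)) {
    paths$qtl <- file.path(dir, "qtl_coloc.tsv")
    utils::write.table(fmt(report$qtl), paths$qtl, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  writeLines(yaml::as.yaml(report$manifest), paths$manifest)
  invisible(paths)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", x$manifest$n_scans, " scans, ",
      nrow(x$loci), " loci kept (", x$clusters$n_clusters,
      " independent), z* = ", format(x$threshold$z_star, digits = 4),
      "\n", sep = "")
  invisible(x)
}
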