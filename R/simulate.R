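# Synthetic multi-trait GWAS summary statistics with the statistical
# structure the analysis assumes: block-diagonal AR(1) LD within traits,
# exchangeable cross-trait null correlation from sample overlap, planted
# shared/trait-specific causal variants, and GTEx-shaped molecular QTLs,
# plus truth tables for parameter-recovery experiments.
#
# The per-trait Z-vector is Z_t = Sigma lambda_t + eps_t where Sigma is the
# LD matrix, lambda_t places each planted non-centrality at its causal
# variant, and the noise has the separable covariance
# (within-trait Sigma) x (cross-trait overlap correlation). Betas and SEs
# are back-filled on the allele-frequency scale via
# se = 1/sqrt(2 n maf (1-maf)), beta = z * se.

#' Block-diagonal AR(1) LD correlation matrix
#'
#' Within each block, `corr(i, j) = rho^|i-j|`; zero across blocks.
#'
#' @param block_sizes integer vector of block sizes.
#' @param rho AR(1) parameter in `[0, 1)`.
#' @return correlation matrix of dimension `sum(block_sizes)`.
#' @export
make_ld_matrix <- function(block_sizes, rho) {
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)", call. = FALSE)
  n <- sum(block_sizes)
  M <- matrix(0, n, n)
  off <- 0
  for (b in block_sizes) {
    idx <- off + seq_len(b)
    M[idx, idx] <- rho^abs(outer(seq_len(b), seq_len(b), "-"))
    off <- off + b
  }
  M
}

#' Simulation configuration
#'
#' Defaults emulate a compact version of the study conditions: two binary
#' atherosclerosis traits plus quantitative risk factors, AR(1) LD blocks,
#' and an exchangeable cross-trait null correlation of 0.3 from sample
#' overlap and shared background.
#'
#' @param traits character trait labels.
#' @param is_binary logical flags, one per trait.
#' @param n_per_trait (effective) sample size per trait.
#' @param n_blocks,block_size LD block layout; variants are placed on one
#'   chromosome with blocks spaced 2 Mb apart (> the 1 Mb locus radius) so
#'   blocks are independent loci.
#' @param within_block_rho AR(1) LD parameter in `[0, 1)`.
#' @param cross_trait_null_corr scalar exchangeable correlation or a full
#'   K-by-K matrix.
#' @param planted_loci list of loci; each is a list with `block` (block
#'   index), `traits` (subset of labels), `ncp` (per-trait non-centrality,
#'   scalar or per-trait vector), `shared` (one causal variant for all
#'   traits, or distinct variants in the same block), and optionally
#'   `known` (emit a catalog entry for its traits at the causal variant)
#'   and `causal_offset` (position of the causal variant within the block,
#'   default mid-block).
#' @param maf_range range of the uniform allele-frequency draw.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(traits = c("PAD", "CAD"),
                       is_binary = c(TRUE, TRUE),
                       n_per_trait = NULL,
                       n_blocks = 40, block_size = 25,
                       within_block_rho = 0.8,
                       cross_trait_null_corr = 0.3,
                       planted_loci = list(),
                       maf_range = c(0.05, 0.5),
                       seed = 1L) {
  K <- length(traits)
  stopifnot(length(is_binary) == K)
  if (is.null(n_per_trait)) n_per_trait <- rep(100000, K)
  C <- if (is.matrix(cross_trait_null_corr)) {
    cross_trait_null_corr
  } else {
    M <- matrix(cross_trait_null_corr, K, K); diag(M) <- 1; M
  }
  stopifnot(nrow(C) == K, ncol(C) == K)
  repair_correlation(C)  # errors if invalid
  for (pl in planted_loci) {
    stopifnot(pl$block >= 1, pl$block <= n_blocks,
              all(pl$traits %in% traits), all(is.finite(pl$ncp)))
  }
  structure(list(traits = traits, is_binary = is_binary,
                 n_per_trait = n_per_trait, n_blocks = n_blocks,
                 block_size = block_size,
                 within_block_rho = within_block_rho,
                 cross_trait_null_corr = C, planted_loci = planted_loci,
                 maf_range = maf_range, seed = seed),
            class = "sim_config")
}

#' @noRd
causal_index <- function(cfg, block, offset = NULL) {
  off <- offset %||% ceiling(cfg$block_size / 2)
  if (off < 1 || off > cfg$block_size) {
    stop("planted causal offset outside its block", call. = FALSE)
  }
  (block - 1) * cfg$block_size + off
}

#' Simulate a multi-trait summary-statistics panel
#'
#' Generates per-trait Z-vectors under the separable LD-by-overlap noise
#' model with planted causal variants, back-fills effect sizes and
#' standard errors, and returns in-memory `trait_scan` objects together
#' with the LD pair table and a truth table. When `dir` is given, the
#' corresponding files (GCTA-`.ma`-style summary statistics, PLINK-style
#' LD table with signed r, catalog and truth TSVs) are also written.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory.
#' @return a `sim_panel`: list with `scans` (list of `trait_scan`),
#'   `ld` (an `ld_table`), `catalog` (data frame, possibly empty),
#'   `truth` (data frame), `variants` (per-variant index), `files`
#'   (paths, when written), `config`.
#' @export
simulate_panel <- function(config, dir = NULL) {
  cfg <- config
  set.seed(cfg$seed)
  K <- length(cfg$traits)
  n_var <- cfg$n_blocks * cfg$block_size
  rho <- cfg$within_block_rho

  # variant frame: blocks 2 Mb apart (> locus radius), 1 kb variant
  # spacing, 100 blocks per synthetic chromosome so positions stay within
  # integer range on large panels
  block_of <- rep(seq_len(cfg$n_blocks), each = cfg$block_size)
  within <- rep(seq_len(cfg$block_size), cfg$n_blocks)
  chrom_of <- as.character((block_of - 1L) %/% 100L + 1L)
  pos <- ((block_of - 1L) %% 100L) * 2000000L + within * 1000L
  alleles <- cbind(c("A", "A", "C", "T"), c("C", "G", "T", "G"))
  ai <- sample.int(4, n_var, replace = TRUE)
  vid <- sprintf("var%05d", seq_len(n_var))
  maf <- stats::runif(n_var, cfg$maf_range[1], cfg$maf_range[2])

  # mean: Sigma %*% lambda per trait, block-local
  lambda <- matrix(0, n_var, K)
  truth <- list()
  catalog <- list()
  for (li in seq_along(cfg$planted_loci)) {
    pl <- cfg$planted_loci[[li]]
    ncp <- rep(pl$ncp, length.out = length(pl$traits))
    shared <- pl$shared %||% TRUE
    ci <- causal_index(cfg, pl$block, pl$causal_offset)
    causal_ids <- character(length(pl$traits))
    for (ti in seq_along(pl$traits)) {
      k <- match(pl$traits[ti], cfg$traits)
      idx <- if (shared) ci else {
        # distinct causal variants for each trait, spread within the block
        cand <- causal_index(cfg, pl$block,
                             ((pl$causal_offset %||%
                                 ceiling(cfg$block_size / 2)) + (ti - 1) * 7 - 1) %%
                               cfg$block_size + 1)
        cand
      }
      lambda[idx, k] <- lambda[idx, k] + ncp[ti]
      causal_ids[ti] <- vid[idx]
    }
    truth[[li]] <- data.frame(
      locus = li, block = pl$block,
      traits = paste(pl$traits, collapse = ","),
      causal = paste(causal_ids, collapse = ","),
      ncp = paste(ncp, collapse = ","),
      shared = shared, known = isTRUE(pl$known),
      stringsAsFactors = FALSE)
    if (isTRUE(pl$known)) {
      catalog[[length(catalog) + 1]] <- data.frame(
        trait = pl$traits, variant_id = causal_ids[1],
        chrom = chrom_of[match(causal_ids[1], vid)],
        pos = pos[match(causal_ids[1], vid)], stringsAsFactors = FALSE)
    }
  }

  # noise: per block L eps, then cross-trait chol
  Ublk <- if (rho > 0) chol(make_ld_matrix(cfg$block_size, rho)) else NULL
  Ccol <- chol(repair_correlation(cfg$cross_trait_null_corr))
  E <- matrix(stats::rnorm(n_var * K), n_var, K) %*% Ccol
  if (!is.null(Ublk)) {
    for (b in seq_len(cfg$n_blocks)) {
      idx <- (b - 1) * cfg$block_size + seq_len(cfg$block_size)
      E[idx, ] <- crossprod(Ublk, E[idx, , drop = FALSE])
    }
  }
  mean_z <- lambda
  if (rho > 0 && any(lambda != 0)) {
    Sig <- make_ld_matrix(cfg$block_size, rho)
    for (b in unique(block_of[rowSums(lambda != 0) > 0])) {
      idx <- (b - 1) * cfg$block_size + seq_len(cfg$block_size)
      mean_z[idx, ] <- Sig %*% lambda[idx, , drop = FALSE]
    }
  }
  Z <- mean_z + E

  scans <- vector("list", K)
  for (k in seq_len(K)) {
    n <- cfg$n_per_trait[k]
    se <- 1 / sqrt(2 * n * maf * (1 - maf))
    v <- data.frame(variant_id = vid, chrom = chrom_of,
                    pos = as.integer(pos),
                    effect_allele = alleles[ai, 1],
                    other_allele = alleles[ai, 2],
                    eaf = maf, beta = Z[, k] * se, se = se, z = Z[, k],
                    p = z_to_p(Z[, k]), n = n, stringsAsFactors = FALSE)
    scans[[k]] <- structure(
      list(trait = cfg$traits[k], is_binary = cfg$is_binary[k],
           n_total = n, variants = v, n_rejected = 0L),
      class = "trait_scan")
  }

  # pairwise LD table (within-block pairs, signed r)
  if (cfg$block_size >= 2) {
    pairs <- do.call(rbind, lapply(seq_len(cfg$n_blocks), function(b) {
      idx <- (b - 1) * cfg$block_size + seq_len(cfg$block_size)
      cmb <- utils::combn(idx, 2)
      data.frame(i = cmb[1, ], j = cmb[2, ], stringsAsFactors = FALSE)
    }))
    r <- rho^abs(within[pairs$i] - within[pairs$j])
  } else {
    pairs <- data.frame(i = integer(), j = integer())
    r <- numeric()
  }
  ld <- ld_table(vid[pairs$i], vid[pairs$j], r^2, r)

  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(locus = integer(), block = integer(), traits = character(),
               causal = character(), ncp = character(), shared = logical(),
               known = logical(), stringsAsFactors = FALSE)
  catalog_df <- if (length(catalog)) do.call(rbind, catalog) else
    data.frame(trait = character(), variant_id = character(),
               chrom = character(), pos = integer(),
               stringsAsFactors = FALSE)

  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- list()
    for (k in seq_len(K)) {
      f <- file.path(dir, paste0("sumstats_", cfg$traits[k], ".tsv"))
      write_sumstats(scans[[k]], f)
      files[[cfg$traits[k]]] <- f
    }
    ldf <- file.path(dir, "ld_pairs.tsv")
    utils::write.table(
      data.frame(CHR_A = chrom_of[pairs$i], BP_A = pos[pairs$i],
                 SNP_A = vid[pairs$i],
                 CHR_B = chrom_of[pairs$j], BP_B = pos[pairs$j],
                 SNP_B = vid[pairs$j],
                 R2 = r^2, R = r),
      ldf, sep = "\t", quote = FALSE, row.names = FALSE)
    files$ld <- ldf
    catf <- file.path(dir, "catalog.tsv")
    utils::write.table(catalog_df, catf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files$catalog <- catf
    trf <- file.path(dir, "truth.tsv")
    utils::write.table(truth_df, trf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files$truth <- trf
  }

  structure(
    list(scans = scans, ld = ld, catalog = catalog_df, truth = truth_df,
         variants = data.frame(variant_id = vid, chrom = chrom_of,
                               pos = as.integer(pos), block = block_of,
                               stringsAsFactors = FALSE),
         files = files, config = cfg),
    class = "sim_panel")
}

#' Simulate a molecular-QTL association for one planted locus
#'
#' Emits a GTEx-shaped significant-pair association over the locus's LD
#' block. When `colocalized`, the QTL's causal variant is the locus's
#' planted causal variant; otherwise a variant in the same block with
#' `r2 < 0.1` to it is chosen (error when the block is too tight to
#' provide one).
#'
#' @param panel a `sim_panel`.
#' @param locus index into `panel$truth`.
#' @param colocalized logical.
#' @param effect_size QTL non-centrality at its causal variant (default 8,
#'   a strong molecular QTL).
#' @param n_qtl QTL study sample size (default 500).
#' @param gene,tissue labels for the emitted pair table.
#' @param seed integer seed.
#' @return list with `assoc` (an `assoc_vector`), `table` (significant-pair
#'   data frame) and `truth` (one-row data frame with the causal key and
#'   the colocalized flag).
#' @export
simulate_molecular_qtl <- function(panel, locus, colocalized = TRUE,
                                   effect_size = 8, n_qtl = 500,
                                   gene = "GENE1", tissue = "tissue1",
                                   seed = 1L) {
  stopifnot(locus >= 1, locus <= nrow(panel$truth))
  cfg <- panel$config
  set.seed(seed)
  tr <- panel$truth[locus, ]
  gwas_causal <- strsplit(tr$causal, ",")[[1]][1]
  b <- tr$block
  idx <- (b - 1) * cfg$block_size + seq_len(cfg$block_size)
  vid <- panel$variants$variant_id[idx]
  pos <- panel$variants$pos[idx]
  ci_local <- match(gwas_causal, vid)
  rho <- cfg$within_block_rho
  if (colocalized) {
    qi <- ci_local
  } else {
    r2 <- rho^(2 * abs(seq_len(cfg$block_size) - ci_local))
    ok <- which(r2 < 0.1)
    if (!length(ok)) {
      stop("no variant with r2 < 0.1 to the GWAS causal variant; ",
           "use a larger block", call. = FALSE)
    }
    qi <- ok[which.min(abs(ok - ci_local))]
  }
  lambda <- numeric(cfg$block_size)
  lambda[qi] <- effect_size
  Sig <- make_ld_matrix(cfg$block_size, rho)
  z <- as.numeric(Sig %*% lambda) +
    as.numeric(crossprod(chol(Sig), stats::rnorm(cfg$block_size)))
  maf <- panel$scans[[1]]$variants$eaf[idx]
  se <- 1 / sqrt(2 * n_qtl * maf * (1 - maf))
  assoc <- assoc_vector(vid, beta = z * se, se = se, pos = pos,
                        label = paste0(gene, ":", tissue))
  tab <- data.frame(gene = gene, tissue = tissue, variant_id = vid,
                    pos = pos, beta = z * se, se = se,
                    stringsAsFactors = FALSE)
  list(assoc = assoc, table = tab,
       truth = data.frame(gene = gene, tissue = tissue,
                          causal = vid[qi], gwas_causal = gwas_causal,
                          colocalized = colocalized,
                          stringsAsFactors = FALSE))
}

#' @export
print.sim_panel <- function(x, ...) {
  cat("<sim_panel> ", length(x$scans), " traits, ",
      nrow(x$variants), " variants in ", x$config$n_blocks,
      " blocks (rho = ", x$config$within_block_rho, "), ",
      nrow(x$truth), " planted loci, seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}
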