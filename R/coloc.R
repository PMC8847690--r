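# Bayesian colocalization via per-variant Wakefield approximate Bayes
# factors, under the single-causal-variant-per-trait assumption.
#
# Pairwise hypotheses (COLOC convention):
#   H0 no association; H1/H2 one trait only; H3 both, distinct causal
#   variants; H4 both, one shared causal variant.
# The trivariate engine enumerates all 15 sharing configurations of three
# traits (each trait null or associated; associated traits partitioned
# among shared causal variants).

#' Wakefield log approximate Bayes factor
#'
#' With `V = se^2`, `W = prior_sd^2`, `r = W/(W+V)` and `z = beta/se`,
#' `log ABF = 0.5 log(1 - r) + r z^2 / 2`, computed in log space so scores
#' up to `|z| ~ 40` do not overflow.
#'
#' @param beta,se effect and standard error (vectorized; `se > 0`).
#' @param prior_sd standard deviation of the normal prior on the true
#'   effect (`> 0`).
#' @return log Bayes factors (association vs null), same length as `beta`.
#' @export
wakefield_log_abf <- function(beta, se, prior_sd) {
  stopifnot(all(se > 0), prior_sd > 0)
  V <- se^2
  r <- prior_sd^2 / (prior_sd^2 + V)
  z <- beta / se
  0.5 * log1p(-r) + r * z^2 / 2
}

#' Construct an association vector
#'
#' Per-variant summary association for one trait (or one gene-tissue QTL)
#' over a shared variant index. Supply `beta` and `se`, or `z` alone under
#' the unit-variance convention (`se = 1`).
#'
#' @param variant_id variant identifiers.
#' @param beta,se effects and standard errors.
#' @param z alternative to `beta`/`se`.
#' @param pos optional positions (needed for windowed colocalization).
#' @param label trait/gene label.
#' @param trait_kind `"quantitative"` or `"case_control"`; selects the ABF
#'   prior SD.
#' @return an `assoc_vector` data frame.
#' @export
assoc_vector <- function(variant_id, beta = NULL, se = NULL, z = NULL,
                         pos = NULL, label = "trait",
                         trait_kind = c("quantitative", "case_control")) {
  trait_kind <- match.arg(trait_kind)
  if (is.null(beta)) {
    stopifnot(!is.null(z))
    beta <- z; se <- rep(1, length(z))
  }
  stopifnot(length(beta) == length(variant_id), all(se > 0))
  out <- data.frame(variant_id = as.character(variant_id), beta = beta,
                    se = se, stringsAsFactors = FALSE)
  if (!is.null(pos)) out$pos <- as.integer(pos)
  structure(out, label = label, trait_kind = trait_kind,
            class = c("assoc_vector", "data.frame"))
}

#' Colocalization priors
#'
#' Per-variant prior probabilities for the sharing configurations, and the
#' effect-scale prior SDs used by the Wakefield ABF. Defaults are the
#' published defaults of the pairwise and trivariate colocalization
#' methods: `p1 = p2 = 1e-4`, `p12 = 1e-5`; for three traits `1e-4`,
#' `1e-6`, `1e-7` for configurations tying a variant to one, two or three
#' traits; prior SD 0.15 for quantitative traits and 0.2 (log-odds) for
#' case-control traits.
#'
#' @param p1,p2,p12 pairwise per-variant priors.
#' @param p_single,p_double,p_triple trivariate per-variant priors by group
#'   size.
#' @param prior_sd_quant,prior_sd_cc effect-scale prior SDs.
#' @return list of priors.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         p_single = 1e-4, p_double = 1e-6, p_triple = 1e-7,
                         prior_sd_quant = 0.15, prior_sd_cc = 0.2) {
  pr <- list(p1 = p1, p2 = p2, p12 = p12, p_single = p_single,
             p_double = p_double, p_triple = p_triple,
             prior_sd_quant = prior_sd_quant, prior_sd_cc = prior_sd_cc)
  stopifnot(all(unlist(pr) > 0), all(unlist(pr[1:6]) < 1))
  if (p12 > min(p1, p2)) {
    warning("p12 exceeds min(p1, p2); shared-causal prior unusually strong",
            call. = FALSE)
  }
  pr
}

#' @noRd
prior_sd_for <- function(assoc, priors) {
  if (identical(attr(assoc, "trait_kind"), "case_control")) {
    priors$prior_sd_cc
  } else {
    priors$prior_sd_quant
  }
}

#' @noRd
window_subset <- function(assoc, sentinel_pos, window_bp) {
  if (is.null(sentinel_pos)) return(assoc)
  stopifnot(!is.null(assoc$pos))
  half <- window_bp / 2
  assoc[abs(assoc$pos - sentinel_pos) <= half, , drop = FALSE]
}

#' @noRd
align_assoc <- function(...) {
  vecs <- list(...)
  ids <- Reduce(intersect, lapply(vecs, function(a) a$variant_id))
  if (length(ids) < 2) stop("fewer than 2 shared variants in window",
                            call. = FALSE)
  lapply(vecs, function(a) a[match(ids, a$variant_id), , drop = FALSE])
}

#' Pairwise Bayesian colocalization
#'
#' Computes per-variant Wakefield ABFs for each trait over the shared
#' variants (optionally restricted to a window centered on a sentinel),
#' sums them over the single-causal-variant configurations of hypotheses
#' H0-H4 with priors `(p1, p2, p12)` via log-sum-exp, and reports the
#' normalized posterior together with the conditional colocalization
#' probability `PP4/(PP3+PP4)`. Verdict bands: `>= 0.8` colocalized,
#' `(0.5, 0.8)` borderline, otherwise distinct.
#'
#' @param a,b `assoc_vector` objects for the two traits.
#' @param priors see [coloc_priors()].
#' @param sentinel_pos optional sentinel position; with `window_bp` it
#'   restricts the analysis to `sentinel_pos +/- window_bp/2` (boundary
#'   variants included).
#' @param window_bp total window width (default 500 kb).
#' @return a `coloc_result`: list with `pp` (named PP0..PP4),
#'   `conditional_prob`, `verdict`, `n_variants`, `undefined` flag.
#' @export
coloc_pairwise <- function(a, b, priors = coloc_priors(),
                           sentinel_pos = NULL, window_bp = 5e5) {
  a <- window_subset(a, sentinel_pos, window_bp)
  b <- window_subset(b, sentinel_pos, window_bp)
  al <- align_assoc(a, b)
  l1 <- wakefield_log_abf(al[[1]]$beta, al[[1]]$se, prior_sd_for(a, priors))
  l2 <- wakefield_log_abf(al[[2]]$beta, al[[2]]$se, prior_sd_for(b, priors))
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  lh <- c(
    PP0 = 0,
    PP1 = log(priors$p1) + s1,
    PP2 = log(priors$p2) + s2,
    PP3 = log(priors$p1) + log(priors$p2) + logdiffexp(s1 + s2, s12),
    PP4 = log(priors$p12) + s12
  )
  finish_coloc(lh, pp_all = "PP4", pp_distinct = "PP3",
               n_variants = length(l1), hypothesis = "pairwise")
}

#' @noRd
finish_coloc <- function(lh, pp_all, pp_distinct, n_variants, hypothesis,
                         configs = NULL) {
  m <- max(lh)
  pp <- exp(lh - m) / sum(exp(lh - m))
  num <- sum(pp[pp_all])
  den <- num + sum(pp[pp_distinct])
  undefined <- den <= 0
  cond <- if (undefined) NA_real_ else num / den
  verdict <- if (undefined || is.na(cond) || cond <= 0.5) {
    "distinct"
  } else if (cond >= 0.8) {
    "colocalized"
  } else {
    "borderline"
  }
  structure(
    list(pp = pp, conditional_prob = cond, verdict = verdict,
         n_variants = n_variants, hypothesis = hypothesis,
         undefined = undefined, configs = configs),
    class = "coloc_result"
  )
}

# All set partitions of the active-trait subsets of {1..3}: each
# configuration is a list of groups; traits in one group share a causal
# variant, groups occupy distinct variants, absent traits are null.
#' @noRd
trivariate_configs <- function(labels) {
  singles <- as.list(seq_along(labels))
  cfgs <- list(list())                                   # null
  for (i in 1:3) cfgs <- c(cfgs, list(list(i)))          # one trait
  for (i in 1:2) for (j in (i + 1):3) {
    cfgs <- c(cfgs, list(list(c(i, j))))                 # two shared
  }
  for (i in 1:2) for (j in (i + 1):3) {
    cfgs <- c(cfgs, list(list(i, j)))                    # two distinct
  }
  cfgs <- c(cfgs, list(list(c(1, 2, 3))))                # all shared
  cfgs <- c(cfgs, list(list(c(1, 2), 3), list(c(1, 3), 2),
                       list(c(2, 3), 1)))                # pair + lone
  cfgs <- c(cfgs, list(list(1, 2, 3)))                   # all distinct
  names(cfgs) <- vapply(cfgs, function(cf) {
    if (!length(cf)) return("null")
    paste(vapply(cf, function(g) paste(labels[g], collapse = ""),
                 character(1)), collapse = ".")
  }, character(1))
  cfgs
}

# log of the sum over assignments of *distinct* variants to the groups of
# a configuration, of prod_g p_{|g|} ABF_g(variant_g); inclusion-exclusion
# over coinciding variants.
#' @noRd
config_log_evidence <- function(cfg, labf, priors) {
  if (!length(cfg)) return(0)
  psize <- c(priors$p_single, priors$p_double, priors$p_triple)
  gl <- lapply(cfg, function(g) rowSums(labf[, g, drop = FALSE]))
  lp <- sum(log(psize[vapply(cfg, length, integer(1))]))
  m <- length(gl)
  if (m == 1) return(lp + logsumexp(gl[[1]]))
  if (m == 2) {
    return(lp + logdiffexp(logsumexp(gl[[1]]) + logsumexp(gl[[2]]),
                           logsumexp(gl[[1]] + gl[[2]])))
  }
  # m == 3: S(x)S(y)S(z) - S(xy)S(z) - S(xz)S(y) - S(yz)S(x) + 2S(xyz)
  S <- function(v) logsumexp(v)
  terms <- c(S(gl[[1]]) + S(gl[[2]]) + S(gl[[3]]),
             S(gl[[1]] + gl[[2]]) + S(gl[[3]]),
             S(gl[[1]] + gl[[3]]) + S(gl[[2]]),
             S(gl[[2]] + gl[[3]]) + S(gl[[1]]),
             log(2) + S(gl[[1]] + gl[[2]] + gl[[3]]))
  lp + signed_logsum(terms, c(1, -1, -1, -1, 1))
}

#' Trivariate Bayesian colocalization
#'
#' Enumerates the 15 sharing configurations of three traits, scores each by
#' summing per-variant ABF products over distinct-variant assignments with
#' group-size priors (`p_single`, `p_double`, `p_triple`), and normalizes.
#' The conditional colocalization probability is the posterior of the
#' full-sharing configuration divided by the total posterior of the five
#' configurations in which every trait carries a signal.
#'
#' @param a,b,c `assoc_vector` objects.
#' @inheritParams coloc_pairwise
#' @return a `coloc_result` with `pp` over all 15 configurations (named by
#'   trait grouping, e.g. `"ab.c"`), `conditional_prob`, `verdict`.
#' @export
moloc_trivariate <- function(a, b, c, priors = coloc_priors(),
                             sentinel_pos = NULL, window_bp = 5e5) {
  a <- window_subset(a, sentinel_pos, window_bp)
  b <- window_subset(b, sentinel_pos, window_bp)
  c <- window_subset(c, sentinel_pos, window_bp)
  al <- align_assoc(a, b, c)
  labf <- cbind(
    wakefield_log_abf(al[[1]]$beta, al[[1]]$se, prior_sd_for(a, priors)),
    wakefield_log_abf(al[[2]]$beta, al[[2]]$se, prior_sd_for(b, priors)),
    wakefield_log_abf(al[[3]]$beta, al[[3]]$se, prior_sd_for(c, priors))
  )
  labels <- c("a", "b", "c")
  cfgs <- trivariate_configs(labels)
  lh <- vapply(cfgs, config_log_evidence, numeric(1), labf = labf,
               priors = priors)
  all_signal <- c("abc", "ab.c", "ac.b", "bc.a", "a.b.c")
  finish_coloc(lh, pp_all = "abc", pp_distinct = setdiff(all_signal, "abc"),
               n_variants = nrow(labf), hypothesis = "trivariate",
               configs = names(cfgs))
}

#' Conditional probability of colocalization
#'
#' `P(shared) / (P(shared) + P(distinct))` - the posterior probability of a
#' shared causal variant given that every trait carries a signal
#' (`PP4/(PP3+PP4)` in the pairwise case). Returns `NA` with a flag when
#' both inputs are zero.
#'
#' @param pp_signal_all posterior mass of the full-sharing hypothesis.
#' @param pp_distinct posterior mass of the all-signals-distinct
#'   hypothesis.
#' @return probability in `[0, 1]`, or `NA_real_` when undefined.
#' @export
conditional_coloc_probability <- function(pp_signal_all, pp_distinct) {
  stopifnot(pp_signal_all >= 0, pp_distinct >= 0)
  tot <- pp_signal_all + pp_distinct
  if (tot == 0) return(NA_real_)
  pp_signal_all / tot
}

#' Approximate conditional Z-score
#'
#' Adjusts a target variant's Z-score for the signal at a conditioning
#' variant using their signed LD correlation:
#' `z_adj = (z_target - r * z_cond) / sqrt(1 - r^2)`.
#'
#' @param z_target z of the variant(s) being adjusted (vectorized).
#' @param z_cond z of the conditioning variant.
#' @param r signed LD correlation(s) between target and conditioning
#'   variant; `|r|` must be below `1 - 1e-6`.
#' @return conditional z-scores.
#' @export
approx_conditional_z <- function(z_target, z_cond, r) {
  if (any(abs(r) >= 1 - 1e-6)) {
    stop("conditioning variant is collinear with target (|r| ~ 1)",
         call. = FALSE)
  }
  (z_target - r * z_cond) / sqrt(1 - r^2)
}

#' Condition an association vector on one variant
#'
#' Applies [approx_conditional_z()] to every variant, using signed LD to
#' the conditioning variant from the LD table; effects are rebuilt on the
#' original se scale (`beta = z_adj * se`) and the conditioning variant
#' itself is removed. With `r = 0` everywhere the remaining statistics are
#' unchanged.
#'
#' @param assoc an `assoc_vector`.
#' @param cond_id variant id to condition on (must be present).
#' @param ld an `ld_table` with signed r available.
#' @return conditioned `assoc_vector`.
#' @export
condition_assoc <- function(assoc, cond_id, ld) {
  i <- match(cond_id, assoc$variant_id)
  if (is.na(i)) stop("conditioning variant not in association vector",
                     call. = FALSE)
  z <- assoc$beta / assoc$se
  r <- ld_r(ld, assoc$variant_id, cond_id)
  zc <- z[i]
  out <- assoc[-i, , drop = FALSE]
  zadj <- approx_conditional_z(z[-i], zc, r[-i])
  assoc_vector(out$variant_id, beta = zadj * out$se, se = out$se,
               pos = out$pos, label = attr(assoc, "label"),
               trait_kind = attr(assoc, "trait_kind"))
}

#' Detect a secondary association signal in a window
#'
#' Automated stand-in for visual regional-plot inspection: any variant with
#' single-trait `p < p_cut` and `r2 < r2_max` with the sentinel flags
#' possible allelic heterogeneity; the most significant such variant is
#' returned.
#'
#' @param assoc an `assoc_vector`.
#' @param sentinel_id sentinel variant id.
#' @param ld an `ld_table`.
#' @param p_cut significance cutoff for the secondary signal (default
#'   `1e-5`).
#' @param r2_max maximum LD with the sentinel (default 0.1).
#' @return variant id of the strongest secondary signal, or `NULL`.
#' @export
detect_secondary_signal <- function(assoc, sentinel_id, ld, p_cut = 1e-5,
                                    r2_max = 0.1) {
  z <- assoc$beta / assoc$se
  p <- z_to_p(z)
  r2 <- ld_r2(ld, assoc$variant_id, sentinel_id)
  cand <- which(p < p_cut & r2 < r2_max & assoc$variant_id != sentinel_id)
  if (!length(cand)) return(NULL)
  assoc$variant_id[cand[which.min(p[cand])]]
}

#' Colocalize a GWAS signal with molecular-QTL signals
#'
#' Runs pairwise colocalization between one GWAS trait and each supplied
#' gene-tissue QTL association over a window spanning the sentinel,
#' recording the direction concordance of the GWAS and QTL effects at the
#' sentinel. Borderline results (conditional probability in (0.5, 0.8))
#' are retried after conditioning the GWAS signal on a detected secondary
#' variant, when an LD table permits.
#'
#' @param gwas `assoc_vector` for the GWAS trait.
#' @param qtl data frame of significant variant-gene pairs (columns
#'   `gene`, `tissue`, `variant_id`, `pos`, `beta`, `se`), or a list of
#'   `assoc_vector`s named `gene:tissue`.
#' @param sentinel_id,sentinel_pos sentinel variant and position.
#' @param priors see [coloc_priors()].
#' @param window_bp total window width (default 500 kb).
#' @param ld optional `ld_table` enabling the conditional-analysis rescue.
#' @return data frame with one row per gene-tissue pair: posterior summary,
#'   conditional probability, verdict, direction concordance and whether
#'   conditioning was applied.
#' @export
qtl_colocalize <- function(gwas, qtl, sentinel_id, sentinel_pos,
                           priors = coloc_priors(), window_bp = 5e5,
                           ld = NULL) {
  if (is.data.frame(qtl)) {
    keys <- unique(qtl[, c("gene", "tissue")])
    qtl_list <- lapply(seq_len(nrow(keys)), function(i) {
      sub <- qtl[qtl$gene == keys$gene[i] & qtl$tissue == keys$tissue[i], ]
      assoc_vector(sub$variant_id, beta = sub$beta, se = sub$se,
                   pos = sub$pos, label = paste0(keys$gene[i], ":",
                                                 keys$tissue[i]))
    })
    names(qtl_list) <- paste(keys$gene, keys$tissue, sep = ":")
  } else {
    qtl_list <- qtl
  }
  if (!length(qtl_list)) {
    return(data.frame(gene = character(), tissue = character(),
                      pp4 = numeric(), conditional_prob = numeric(),
                      verdict = character(), concordance = character(),
                      conditioned = logical(), stringsAsFactors = FALSE))
  }
  rows <- lapply(names(qtl_list), function(nm) {
    qa <- qtl_list[[nm]]
    res <- coloc_pairwise(gwas, qa, priors, sentinel_pos, window_bp)
    conditioned <- FALSE
    if (identical(res$verdict, "borderline") && !is.null(ld)) {
      sec <- detect_secondary_signal(gwas, sentinel_id, ld)
      if (!is.null(sec)) {
        res2 <- coloc_pairwise(condition_assoc(gwas, sec, ld), qa, priors,
                               sentinel_pos, window_bp)
        res <- res2
        conditioned <- TRUE
      }
    }
    gi <- match(sentinel_id, gwas$variant_id)
    qi <- match(sentinel_id, qa$variant_id)
    conc <- if (is.na(gi) || is.na(qi)) {
      NA_character_
    } else {
      paste0(ifelse(gwas$beta[gi] >= 0, "+", "-"), "/",
             ifelse(qa$beta[qi] >= 0, "+", "-"))
    }
    gt <- strsplit(nm, ":", fixed = TRUE)[[1]]
    data.frame(gene = gt[1], tissue = gt[2],
               pp4 = unname(res$pp["PP4"]),
               conditional_prob = res$conditional_prob,
               verdict = res$verdict, concordance = conc,
               conditioned = conditioned, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a significant variant-gene QTL pair table
#'
#' Tab-delimited `gene tissue variant_id pos beta se`, the shape of
#' GTEx-style significant-pair tables.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_qtl_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "tissue", "variant_id", "pos", "beta", "se")
                %in% names(tab)))
  tab
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("<coloc_result> ", x$hypothesis, ", ", x$n_variants, " variants; ",
      "conditional P(shared | both signals) = ",
      ifelse(is.na(x$conditional_prob), "NA",
             format(x$conditional_prob, digits = 3)),
      " -> ", x$verdict, "\n", sep = "")
  top <- sort(x$pp, decreasing = TRUE)[1:min(5, length(x$pp))]
  cat("  top posteriors: ",
      paste(names(top), format(top, digits = 3), sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
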