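# N-weighted multivariate meta-analysis (N-GWAMA) of correlated Z-scores.
#
# For a variant with per-trait scores z and sample sizes n, the combined
# statistic is
#   z_multi = sum_i sqrt(n_i) z_i / sqrt(sum_ij sqrt(n_i n_j) R_ij)
# where R is the cross-trait correlation of null Z-scores (sample overlap
# plus shared genetic background). At R = I and equal n this reduces to
# sample-size-weighted fixed-effect meta-analysis, (sum z)/sqrt(K).

#' Enumerate the multi-trait scan design
#'
#' Given a core pair of disease traits and a list of risk-factor traits,
#' returns the core bivariate scan, one trivariate scan per risk trait
#' (core + risk), and one bivariate scan of the first core trait with each
#' risk trait, in that deterministic order. Two core traits and seven risk
#' traits therefore yield 15 scans.
#'
#' @param core character vector of exactly two trait labels.
#' @param risk character vector of risk-factor trait labels (may be empty).
#' @return list of `scan_definition` objects (fields `label`, `traits`).
#' @examples
#' length(enumerate_scans(c("PAD", "CAD"),
#'                        c("BMI", "SMK", "T2D", "LDL", "HDL", "TC", "TG")))
#' @export
enumerate_scans <- function(core, risk = character()) {
  stopifnot(length(core) == 2)
  all_traits <- c(core, risk)
  if (anyDuplicated(all_traits)) {
    stop("duplicate trait labels in scan design", call. = FALSE)
  }
  mk <- function(traits) {
    structure(list(label = paste(traits, collapse = ","), traits = traits),
              class = "scan_definition")
  }
  out <- list(mk(core))
  for (r in risk) out <- c(out, list(mk(c(core, r))))
  for (r in risk) out <- c(out, list(mk(c(core[1], r))))
  out
}

#' Estimate the cross-trait Z-score correlation
#'
#' Pairwise Pearson correlation of the panel's z columns, optionally
#' restricted to variants with `|z| <` a cutoff in both traits of a pair
#' (a null-restricted estimate that avoids inflation from strong signals).
#' The result is repaired to the nearest positive semi-definite correlation
#' matrix by eigenvalue clipping when needed.
#'
#' @param panel a `harmonized_panel`.
#' @param null_restrict numeric |z| cutoff, or `NULL` (default) to use all
#'   shared variants.
#' @return a `cross_trait_corr`: list with `traits` and `matrix`.
#' @export
estimate_z_correlation <- function(panel, null_restrict = NULL) {
  Z <- panel$z_matrix
  K <- ncol(Z)
  if (nrow(Z) < 1000) {
    warning("fewer than 1000 shared variants; correlation estimate may be noisy",
            call. = FALSE)
  }
  R <- diag(1, K)
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      zi <- Z[, i]; zj <- Z[, j]
      use <- !is.na(zi) & !is.na(zj)
      if (!is.null(null_restrict)) {
        use <- use & abs(zi) < null_restrict & abs(zj) < null_restrict
      }
      if (sum(use) < 3) {
        stop("fewer than 3 usable variants for pair ",
             panel$traits[i], "/", panel$traits[j], call. = FALSE)
      }
      R[i, j] <- R[j, i] <- stats::cor(zi[use], zj[use])
    }
  }
  R <- repair_correlation(R)
  dimnames(R) <- list(panel$traits, panel$traits)
  structure(list(traits = panel$traits, matrix = R),
            class = "cross_trait_corr")
}

#' Combine per-trait Z-scores into a multivariate statistic
#'
#' Applies the N-weighted combination with weights `w_i = sqrt(n_i)` and a
#' denominator `sqrt(w' R w)` that accounts for cross-trait correlation.
#'
#' @param z numeric vector of K per-trait z-scores, or a variants-by-K
#'   matrix to combine row-wise.
#' @param n sample sizes: a K-vector, or a matrix conformable with `z`.
#' @param R K-by-K cross-trait correlation matrix (or a
#'   `cross_trait_corr`).
#' @return list with `z_multi` and `p_multi` (two-sided), each of length
#'   `nrow(z)` (or 1 for vector input).
#' @export
ngwama_combine <- function(z, n, R) {
  if (inherits(R, "cross_trait_corr")) R <- R$matrix
  zm <- if (is.matrix(z)) z else matrix(z, nrow = 1)
  K <- ncol(zm)
  stopifnot(nrow(R) == K, ncol(R) == K)
  nm <- if (is.matrix(n)) n else matrix(n, nrow(zm), K, byrow = TRUE)
  stopifnot(all(nm > 0))
  W <- sqrt(nm)
  num <- rowSums(W * zm)
  den2 <- rowSums((W %*% R) * W)
  if (any(den2 <= 0)) {
    stop("non-positive combination variance w'Rw; check the correlation matrix",
         call. = FALSE)
  }
  z_multi <- num / sqrt(den2)
  list(z_multi = z_multi, p_multi = z_to_p(z_multi))
}

#' Run one multi-trait scan over a harmonized panel
#'
#' Restricts the panel to the scan's traits (complete-case), combines the
#' per-variant z-scores with [ngwama_combine()] and attaches per-trait
#' single z/p and a direction string (one sign per scan trait).
#'
#' @param panel a `harmonized_panel`.
#' @param scan a `scan_definition` (or character vector of trait labels).
#' @param R a `cross_trait_corr` over (at least) the scan's traits.
#' @return a `multitrait_result`: data frame with the panel index columns,
#'   `z_multi`, `p_multi`, per-trait `z.*` / `p.*` columns and `direction`;
#'   the scan definition is attached as attribute `scan`.
#' @export
scan_panel <- function(panel, scan, R) {
  traits <- if (inherits(scan, "scan_definition")) scan$traits else scan
  stopifnot(all(traits %in% panel$traits))
  Rm <- if (inherits(R, "cross_trait_corr")) R$matrix else R
  Rs <- Rm[traits, traits, drop = FALSE]
  Z <- panel$z_matrix[, traits, drop = FALSE]
  N <- panel$n_matrix[, traits, drop = FALSE]
  keep <- stats::complete.cases(Z) & stats::complete.cases(N)
  Z <- Z[keep, , drop = FALSE]
  N <- N[keep, , drop = FALSE]
  comb <- ngwama_combine(Z, N, Rs)
  out <- panel$index[keep, , drop = FALSE]
  out$z_multi <- comb$z_multi
  out$p_multi <- comb$p_multi
  for (t in traits) {
    out[[paste0("z.", t)]] <- Z[, t]
    out[[paste0("p.", t)]] <- z_to_p(Z[, t])
  }
  out$direction <- apply(Z, 1, function(zz) {
    paste(ifelse(zz >= 0, "+", "-"), collapse = "/")
  })
  rownames(out) <- NULL
  sd <- if (inherits(scan, "scan_definition")) scan else
    structure(list(label = paste(traits, collapse = ","), traits = traits),
              class = "scan_definition")
  structure(out, scan = sd, n_excluded = sum(!keep),
            class = c("multitrait_result", "data.frame"))
}

#' Correlation between scans' multivariate statistics
#'
#' Pearson correlation of the `z_multi` columns of several scan results over
#' the intersection of their variant keys; this is the scan-level null
#' correlation fed to the resampling significance threshold.
#'
#' @param results list of `multitrait_result` objects.
#' @return a `cross_trait_corr` whose labels are scan labels.
#' @export
scan_correlation <- function(results) {
  labels <- vapply(results, function(r) attr(r, "scan")$label, character(1))
  keys <- Reduce(intersect, lapply(results, function(r) r$key))
  if (length(keys) < 3) stop("fewer than 3 variants shared across scans",
                             call. = FALSE)
  Z <- vapply(results, function(r) r$z_multi[match(keys, r$key)],
              numeric(length(keys)))
  R <- repair_correlation(stats::cor(Z))
  dimnames(R) <- list(labels, labels)
  structure(list(traits = labels, matrix = R), class = "cross_trait_corr")
}

#' @export
print.scan_definition <- function(x, ...) {
  cat("<scan> ", x$label, "\n", sep = "")
  invisible(x)
}
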