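# Experiment-wide significance: Bonferroni comparator and the empirical
# max-|Z| resampling threshold from a correlated multivariate normal null.

#' Two-sided p-value of a Z-score
#'
#' `2 * P(|N(0,1)| > |z|)`, computed on the upper tail directly so there is
#' no `1 - CDF` cancellation at large `|z|`.
#'
#' @param z numeric vector of signed scores.
#' @return two-sided tail probabilities in `(0, 1]`.
#' @examples
#' z_to_p(5.87)
#' @export
z_to_p <- function(z) {
  2 * stats::pnorm(abs(z), lower.tail = FALSE)
}

#' Z-score corresponding to a two-sided p-value
#'
#' @param p probabilities in `(0, 1]`.
#' @return positive z such that `z_to_p(z) == p`.
#' @export
p_to_z <- function(p) {
  stats::qnorm(p / 2, lower.tail = FALSE)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha_gw per-scan genome-wide alpha (e.g. `5e-8`).
#' @param n_scans number of scans.
#' @return `alpha_gw / n_scans`.
#' @examples
#' bonferroni_threshold(5e-8, 15)
#' @export
bonferroni_threshold <- function(alpha_gw, n_scans) {
  stopifnot(alpha_gw > 0, alpha_gw < 1, n_scans >= 1)
  alpha_gw / n_scans
}

#' Empirical experiment-wide threshold by max-|Z| resampling
#'
#' Draws `n_sets` sets of `set_size` independent K-vectors from
#' `MVN(0, R)`, where `R` is the correlation between the K scans' null
#' Z-scores, keeps the most extreme `|z|` in each set, and returns the
#' requested percentile of the set maxima as the experiment-wide Z
#' threshold `z_star` with its two-sided p-value `p_star`. Sampling is
#' chunked so memory stays bounded at any `set_size`, and is fully
#' reproducible from `seed`.
#'
#' The set maxima quantile uses linear interpolation between order
#' statistics (type 7).
#'
#' @param R K-by-K scan correlation matrix (or a `cross_trait_corr`);
#'   repaired to the nearest positive semi-definite correlation if needed.
#' @param set_size M, number of multivariate draws per set (the study-scale
#'   analogue is the number of variants tested genome-wide).
#' @param n_sets S, number of sets.
#' @param percentile quantile of the set maxima to report (default 0.95,
#'   i.e. family-wise alpha 0.05).
#' @param seed integer RNG seed.
#' @param chunk_size draws sampled per block within a set.
#' @return a `threshold_estimate`: list with `z_star`, `p_star`,
#'   `percentile`, `n_sets`, `set_size`, `scan_correlation`, `seed`.
#' @export
resampling_threshold <- function(R, set_size, n_sets, percentile = 0.95,
                                 seed = 1L, chunk_size = 250000L) {
  if (inherits(R, "cross_trait_corr")) R <- R$matrix
  stopifnot(set_size >= 1, n_sets >= 1, percentile > 0, percentile < 1)
  R <- repair_correlation(R)
  K <- nrow(R)
  # symmetric square root via eigendecomposition: handles semi-definite R
  # (e.g. perfectly correlated scans) where a Cholesky factor would fail
  e <- eigen(R, symmetric = TRUE)
  U <- sqrt(pmax(e$values, 0)) * t(e$vectors)  # t(U) %*% U == R
  set.seed(seed)
  maxima <- numeric(n_sets)
  for (s in seq_len(n_sets)) {
    remaining <- set_size
    m <- 0
    while (remaining > 0) {
      nb <- min(remaining, chunk_size)
      X <- matrix(stats::rnorm(nb * K), nb, K) %*% U
      m <- max(m, max(abs(X)))
      remaining <- remaining - nb
    }
    maxima[s] <- m
  }
  z_star <- unname(stats::quantile(maxima, percentile, type = 7))
  structure(
    list(z_star = z_star, p_star = z_to_p(z_star), percentile = percentile,
         n_sets = n_sets, set_size = set_size, scan_correlation = R,
         seed = seed),
    class = "threshold_estimate"
  )
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat("<threshold_estimate> z* = ", format(x$z_star, digits = 4),
      " (p* = ", format(x$p_star, digits = 3), "), ",
      100 * x$percentile, "th percentile of ", x$n_sets, " sets of ",
      x$set_size, " draws, K = ", nrow(x$scan_correlation),
      ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}
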