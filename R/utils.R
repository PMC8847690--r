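# Internal numeric helpers shared across modules.

#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference
# underflows (the two sums agree to within double precision).
#' @noRd
logdiffexp <- function(a, b) {
  if (b == -Inf) return(a)
  if (a < b) stop("logdiffexp: a < b", call. = FALSE)
  d <- -expm1(b - a)
  if (d <= 0) return(-Inf)
  a + log(d)
}

# Signed accumulation of exp(l) * s terms (s in {-1, +1}), in a shifted
# linear scale; returns the log of the (clipped-at-zero) total.
#' @noRd
signed_logsum <- function(l, s) {
  keep <- l > -Inf
  l <- l[keep]; s <- s[keep]
  if (!length(l)) return(-Inf)
  m <- max(l)
  tot <- sum(s * exp(l - m))
  if (tot <= 0) return(-Inf)
  m + log(tot)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical variant key: chromosome, position and the unordered allele pair.
# Robust to rsID drift and to which allele was chosen as "effect".
#' @noRd
variant_key <- function(chrom, pos, a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  paste(chrom, pos, pmin(a1, a2), pmax(a1, a2), sep = ":")
}

#' @noRd
is_strand_ambiguous <- function(a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# Nearest-correlation repair: symmetrize, clip eigenvalues at zero and
# rescale to unit diagonal. Errors when the input is too indefinite for a
# clip to be an honest repair.
#' @noRd
repair_correlation <- function(R, max_negative = 0.1) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -max_negative) {
    stop("correlation matrix is indefinite beyond repair tolerance (min eigenvalue ",
         signif(min(e$values), 3), ")", call. = FALSE)
  }
  if (min(e$values) >= 0) {
    diag(R) <- 1
    return(R)
  }
  v <- pmax(e$values, 0)
  R2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  diag(R2) <- 1
  (R2 + t(R2)) / 2
}
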