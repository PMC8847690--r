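# Independent brute-force oracles. These deliberately use plain loops and
# direct summation so they share no code path with the package's
# log-sum-exp engines.

# Pairwise colocalization by explicit enumeration of single-causal-variant
# configurations.
oracle_coloc_pairwise <- function(labf1, labf2, p1, p2, p12) {
  n <- length(labf1)
  b1 <- exp(labf1)
  b2 <- exp(labf2)
  h0 <- 1
  h1 <- 0; for (i in 1:n) h1 <- h1 + p1 * b1[i]
  h2 <- 0; for (j in 1:n) h2 <- h2 + p2 * b2[j]
  h3 <- 0
  for (i in 1:n) for (j in 1:n) if (i != j) h3 <- h3 + p1 * p2 * b1[i] * b2[j]
  h4 <- 0; for (i in 1:n) h4 <- h4 + p12 * b1[i] * b2[i]
  h <- c(PP0 = h0, PP1 = h1, PP2 = h2, PP3 = h3, PP4 = h4)
  h / sum(h)
}

# Trivariate colocalization by explicit enumeration over all 15 sharing
# configurations and all distinct-variant assignments.
oracle_moloc_trivariate <- function(labf1, labf2, labf3,
                                    p1 = 1e-4, p2 = 1e-6, p3 = 1e-7) {
  n <- length(labf1)
  b <- cbind(exp(labf1), exp(labf2), exp(labf3))
  grp <- function(g, i) prod(b[i, g])
  ev <- c(null = 1)
  # single active groups (subsets of traits sharing one variant)
  subsets <- list(a = 1, b = 2, c = 3, ab = c(1, 2), ac = c(1, 3),
                  bc = c(2, 3), abc = c(1, 2, 3))
  psize <- c(p1, p2, p3)
  for (nm in names(subsets)) {
    g <- subsets[[nm]]
    s <- 0
    for (i in 1:n) s <- s + psize[length(g)] * grp(g, i)
    ev[nm] <- s
  }
  # two groups, distinct variants
  two <- list(`a.b` = list(1, 2), `a.c` = list(1, 3), `b.c` = list(2, 3),
              `ab.c` = list(c(1, 2), 3), `ac.b` = list(c(1, 3), 2),
              `bc.a` = list(c(2, 3), 1))
  for (nm in names(two)) {
    gs <- two[[nm]]
    s <- 0
    for (i in 1:n) for (j in 1:n) if (i != j) {
      s <- s + psize[length(gs[[1]])] * psize[length(gs[[2]])] *
        grp(gs[[1]], i) * grp(gs[[2]], j)
    }
    ev[nm] <- s
  }
  # three singleton groups, all distinct
  s <- 0
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    if (i != j && i != k && j != k) {
      s <- s + p1^3 * b[i, 1] * b[j, 2] * b[k, 3]
    }
  }
  ev["a.b.c"] <- s
  ev / sum(ev)
}

# Reference sentinel selection: repeatedly rescan the full significant list
# for the smallest unclaimed p (ties by chrom then pos), then mark its
# window/LD members claimed.
oracle_sentinels <- function(df, p_threshold, ld = NULL, window_bp = 1e6,
                             r2_min = 0.2) {
  claimed <- rep(FALSE, nrow(df))
  out <- character()
  repeat {
    cand <- which(!claimed & df$p_multi < p_threshold)
    if (!length(cand)) break
    o <- cand[order(df$p_multi[cand], df$chrom[cand], df$pos[cand])][1]
    out <- c(out, df$key[o])
    for (i in seq_len(nrow(df))) {
      near <- df$chrom[i] == df$chrom[o] &&
        abs(df$pos[i] - df$pos[o]) <= window_bp
      inld <- if (!is.null(ld)) {
        ld_r2(ld, df$variant_id[i], df$variant_id[o]) > r2_min
      } else {
        FALSE
      }
      if (near || inld) claimed[i] <- TRUE
    }
  }
  out
}

# Sidak closed form: 95th-percentile two-sided p for the max of n_eff
# independent standard normal tests.
sidak_p_star <- function(n_eff, percentile = 0.95) {
  1 - percentile^(1 / n_eff)
}
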