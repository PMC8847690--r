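test_that("Wakefield log ABF matches its closed form", {
  # beta=0.5, se=0.1, prior_sd=0.2: r=0.8, z=5, labf = 10 + 0.5 log(0.2)
  expect_equal(wakefield_log_abf(0.5, 0.1, 0.2),
               10 + 0.5 * log(0.2), tolerance = 1e-12)
  # null effect shrinks: labf = 0.5 log(1-r) < 0
  r <- 0.2^2 / (0.2^2 + 0.1^2)
  expect_equal(wakefield_log_abf(0, 0.1, 0.2), 0.5 * log(1 - r))
  expect_lt(wakefield_log_abf(0, 0.1, 0.2), 0)
  # degenerate prior: labf -> 0 for any z
  expect_equal(wakefield_log_abf(0.5, 0.1, 1e-9), 0, tolerance = 1e-6)
  # log-space stability far into the tail
  expect_true(is.finite(wakefield_log_abf(40, 1, 0.15)))
})

test_that("pairwise posteriors match exhaustive enumeration to 1e-10", {
  set.seed(23)
  pr <- coloc_priors()
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    z1 <- rnorm(n, sd = 2); z2 <- rnorm(n, sd = 2)
    if (rep %% 3 == 0) {  # sometimes plant a strong shared variant
      z1[1] <- 8; z2[1] <- 8
    }
    a <- make_assoc(z1, "a"); b <- make_assoc(z2, "b")
    res <- coloc_pairwise(a, b, pr)
    l1 <- wakefield_log_abf(z1 * 0.03, rep(0.03, n), pr$prior_sd_quant)
    l2 <- wakefield_log_abf(z2 * 0.03, rep(0.03, n), pr$prior_sd_quant)
    orc <- oracle_coloc_pairwise(l1, l2, pr$p1, pr$p2, pr$p12)
    expect_lt(max(abs(res$pp - orc)), 1e-10)
    expect_equal(sum(res$pp), 1, tolerance = 1e-9)
  }
})

test_that("trivariate posteriors match exhaustive enumeration to 1e-10", {
  set.seed(29)
  pr <- coloc_priors()
  for (rep in 1:12) {
    n <- sample(3:10, 1)
    Z <- matrix(rnorm(3 * n, sd = 2), n, 3)
    if (rep %% 4 == 0) Z[1, ] <- 7    # shared strong signal
    if (rep %% 4 == 1) {              # two share, one distinct
      Z[1, 1:2] <- 7; Z[min(2, n), 3] <- 6
    }
    a <- make_assoc(Z[, 1], "a"); b <- make_assoc(Z[, 2], "b")
    c3 <- make_assoc(Z[, 3], "c")
    res <- moloc_trivariate(a, b, c3, pr)
    labf <- vapply(1:3, function(k) {
      wakefield_log_abf(Z[, k] * 0.03, rep(0.03, n), pr$prior_sd_quant)
    }, numeric(n))
    orc <- oracle_moloc_trivariate(labf[, 1], labf[, 2], labf[, 3],
                                   pr$p_single, pr$p_double, pr$p_triple)
    expect_equal(sum(res$pp), 1, tolerance = 1e-9)
    expect_lt(max(abs(res$pp[names(orc)] - orc)), 1e-10)
  }
})

test_that("strong shared signals colocalize; null windows favour H0", {
  set.seed(31)
  n <- 50
  z1 <- rnorm(n); z2 <- rnorm(n)
  z1[25] <- 8; z2[25] <- 8
  res <- coloc_pairwise(make_assoc(z1), make_assoc(z2))
  expect_gte(res$conditional_prob, 0.8)
  expect_equal(res$verdict, "colocalized")
  res0 <- coloc_pairwise(make_assoc(rep(0, n)), make_assoc(rep(0, n)))
  expect_gt(res0$pp["PP0"], 0.9)
  # distinct causal variants: high PP3, low conditional probability
  z3 <- rnorm(n); z4 <- rnorm(n)
  z3[10] <- 8; z4[40] <- 8
  res2 <- coloc_pairwise(make_assoc(z3), make_assoc(z4))
  expect_equal(res2$verdict, "distinct")
  expect_lt(res2$conditional_prob, 0.5)
})

test_that("trivariate engine concentrates on the planted configuration", {
  set.seed(37)
  n <- 30
  z <- replicate(3, rnorm(n))
  z[15, ] <- 8
  res <- moloc_trivariate(make_assoc(z[, 1]), make_assoc(z[, 2]),
                          make_assoc(z[, 3]))
  expect_equal(names(which.max(res$pp)), "abc")
  expect_gte(res$conditional_prob, 0.8)
  expect_equal(res$verdict, "colocalized")
  # third trait null: posterior lands on "ab.c-null" style sharing and the
  # a/b sharing marginal agrees with the pairwise run
  z2 <- replicate(3, rnorm(n))
  z2[15, 1:2] <- 8
  res2 <- moloc_trivariate(make_assoc(z2[, 1]), make_assoc(z2[, 2]),
                           make_assoc(z2[, 3]))
  expect_equal(names(which.max(res2$pp)), "ab")
  pair <- coloc_pairwise(make_assoc(z2[, 1]), make_assoc(z2[, 2]))
  shared_ab <- sum(res2$pp[c("ab", "ab.c", "abc")])
  expect_lt(abs(shared_ab - pair$pp["PP4"]), 0.05)
})

test_that("raising the shared prior never decreases PP4", {
  set.seed(41)
  z1 <- rnorm(20); z2 <- rnorm(20)
  z1[5] <- 4; z2[5] <- 4.5
  a <- make_assoc(z1); b <- make_assoc(z2)
  pp4 <- vapply(c(1e-6, 1e-5, 1e-4), function(p12) {
    unname(coloc_pairwise(a, b, coloc_priors(p12 = p12))$pp["PP4"])
  }, numeric(1))
  expect_true(all(diff(pp4) > 0))
})

test_that("conditional colocalization probability handles edge cases", {
  expect_equal(conditional_coloc_probability(0.4, 0.1), 0.8)
  expect_equal(conditional_coloc_probability(0, 0.5), 0)
  expect_true(is.na(conditional_coloc_probability(0, 0)))
})

test_that("approximate conditional z matches its closed form and guards collinearity", {
  expect_equal(approx_conditional_z(6, 5, 0.8), (6 - 4) / 0.6,
               tolerance = 1e-12)
  expect_equal(approx_conditional_z(c(1, -2), 5, 0), c(1, -2))
  expect_error(approx_conditional_z(6, 5, 1), "collinear")
  expect_error(approx_conditional_z(6, 5, -0.9999999), "collinear")
})

test_that("conditioning on an r=0 variant leaves colocalization unchanged", {
  set.seed(43)
  z1 <- rnorm(30); z2 <- rnorm(30)
  z1[10] <- 7; z2[10] <- 7
  a <- make_assoc(z1)
  ld <- ld_table("v001", "v002", 0, 0)  # all pairs default to r = 0
  ld$default_r2 <- 0
  base <- coloc_pairwise(a, make_assoc(z2))
  cond <- coloc_pairwise(condition_assoc(a, "v030", ld), make_assoc(z2))
  # removing one null variant and conditioning at r = 0 is a no-op on the
  # remaining z's; posteriors agree to numerical precision
  expect_lt(abs(base$conditional_prob - cond$conditional_prob), 1e-3)
})

test_that("secondary-signal rescue recovers colocalization under allelic heterogeneity", {
  # trait A and B share causal variant v10; trait B carries an extra
  # independent signal at v40 (r ~ 0 with v10), which violates the
  # single-causal assumption and drags the conditional probability down
  set.seed(47)
  n <- 50
  pos <- seq_len(n) * 1000L
  ids <- sprintf("v%03d", seq_len(n))
  z_shared <- rnorm(n, sd = 0.8)
  z_shared[10] <- 7.5
  zb <- rnorm(n, sd = 0.8)
  zb[10] <- 4.8   # the shared signal is the weaker one in trait B
  zb[40] <- 7
  a <- make_assoc(z_shared, "A", pos)
  b <- make_assoc(zb, "B", pos)
  ld <- ld_table(ids[c(1, 2)], ids[c(2, 3)], c(0, 0), c(0, 0))
  base <- coloc_pairwise(a, b)
  expect_lt(base$conditional_prob, 0.8)
  sec <- detect_secondary_signal(b, "v010", ld)
  expect_equal(sec, "v040")
  b_cond <- condition_assoc(b, sec, ld)
  rescued <- coloc_pairwise(a, b_cond)
  expect_gte(rescued$conditional_prob, 0.8)
})

test_that("QTL colocalization follows the generator truth table", {
  cfg <- sim_config(traits = c("PAD", "CAD"), is_binary = c(TRUE, TRUE),
                    n_blocks = 6, block_size = 41,
                    planted_loci = list(list(block = 3,
                                             traits = c("PAD", "CAD"),
                                             ncp = 7, shared = TRUE)),
                    seed = 53)
  pan <- simulate_panel(cfg)
  hp <- harmonize_panel(pan$scans)
  gwas <- pleioscan:::assoc_from_panel(hp, "PAD", is_binary = TRUE)
  tr <- pan$truth[1, ]
  sentinel <- strsplit(tr$causal, ",")[[1]][1]
  spos <- pan$variants$pos[match(sentinel, pan$variants$variant_id)]
  qc <- simulate_molecular_qtl(pan, 1, colocalized = TRUE, seed = 7)
  qd <- simulate_molecular_qtl(pan, 1, colocalized = FALSE, seed = 8,
                               gene = "GENE2")
  out <- qtl_colocalize(gwas, rbind(qc$table, qd$table), sentinel, spos)
  expect_equal(out$verdict[out$gene == "GENE1"], "colocalized")
  expect_equal(out$verdict[out$gene == "GENE2"], "distinct")
  expect_true(all(grepl("^[+-]/[+-]$", out$concordance)))
  # direction concordance reflects the signs at the sentinel
  gi <- match(sentinel, gwas$variant_id)
  qi <- match(sentinel, qc$assoc$variant_id)
  expect_equal(out$concordance[out$gene == "GENE1"],
               paste0(ifelse(gwas$beta[gi] >= 0, "+", "-"), "/",
                      ifelse(qc$assoc$beta[qi] >= 0, "+", "-")))
})
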