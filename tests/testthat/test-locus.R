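make_result <- function(chrom, pos, p_multi, ids = NULL,
                        traits = c("A", "B"), p_traits = NULL) {
  n <- length(pos)
  ids <- ids %||% sprintf("s%03d", seq_len(n))
  pos <- as.integer(pos)
  df <- data.frame(key = paste0(chrom, ":", pos), chrom = chrom,
                   pos = pos, variant_id = ids,
                   effect_allele = "A", other_allele = "G", eaf = 0.3,
                   z_multi = p_to_z(p_multi), p_multi = p_multi,
                   stringsAsFactors = FALSE)
  for (i in seq_along(traits)) {
    df[[paste0("p.", traits[i])]] <-
      if (is.null(p_traits)) rep(1e-4, n) else p_traits[[i]]
    df[[paste0("z.", traits[i])]] <- 1
  }
  df$direction <- paste(rep("+", length(traits)), collapse = "/")
  structure(df,
            scan = structure(list(label = paste(traits, collapse = ","),
                                  traits = traits),
                             class = "scan_definition"),
            class = c("multitrait_result", "data.frame"))
}

test_that("greedy sentinel selection claims nearby signals", {
  res <- make_result("1", c(1e6, 1.2e6), c(1e-10, 1e-9))
  expect_equal(find_sentinels(res, 5e-8), "1:1000000")
  # different chromosomes: two sentinels
  res2 <- make_result(c("1", "2"), c(1e6, 1e6), c(1e-10, 1e-9))
  expect_length(find_sentinels(res2, 5e-8), 2)
  # nothing significant
  expect_length(find_sentinels(make_result("1", 1e6, 1e-3), 5e-8), 0)
})

test_that("greedy selection equals the rescanning reference on random instances", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(5:20, 1)
    chrom <- sample(c("1", "2"), n, TRUE)
    pos <- sample.int(5e6, n)
    p <- 10^runif(n, -12, -4)
    ids <- sprintf("r%02d", seq_len(n))
    ld <- ld_table(sample(ids, 3), sample(ids, 3), runif(3, 0.3, 0.9))
    res <- make_result(chrom, pos, p, ids)
    expect_identical(find_sentinels(res, 5e-8, ld),
                     oracle_sentinels(res, 5e-8, ld))
  }
})

test_that("locus membership uses the window rule plus the LD pull-in", {
  ids <- c("sent", "near", "far_ld", "far")
  res <- make_result("1", c(10e6, 10.9e6, 11.5e6, 11.5e6 + 1), c(
    1e-12, 1e-5, 1e-5, 1e-5), ids)
  ld <- ld_table(c("sent", "sent"), c("far_ld", "far"), c(0.3, 0.1))
  loc <- define_locus(res$key[1], res, ld)
  members <- res$variant_id[match(loc$members, res$key)]
  expect_true(all(c("sent", "near", "far_ld") %in% members))
  expect_false("far" %in% members)
  expect_true(loc$sentinel$key %in% loc$members)
})

test_that("pleiotropy filters implement the strict single-trait window", {
  # the published PCSK6-locus sentinel passes both verdicts
  res <- make_result("15", 101906737, 3.15e-10, "rs1531817",
                     traits = c("PAD", "LDL"),
                     p_traits = list(4.72e-4, 6.48e-8))
  loc <- define_locus(res$key[1], res)
  loc <- apply_pleiotropy_filters(loc)
  expect_true(loc$verdicts$pleiotropy_pass)
  expect_true(loc$verdicts$not_gw_single)
  expect_true(loc$verdicts$outside_hla)
  # one trait at p = 0.01: not pleiotropic
  l2 <- apply_pleiotropy_filters(loc, c(PAD = 0.01, LDL = 1e-4))
  expect_false(l2$verdicts$pleiotropy_pass)
  # one trait genome-wide significant: fails the not-GW filter
  l3 <- apply_pleiotropy_filters(loc, c(PAD = 1e-9, LDL = 1e-4))
  expect_false(l3$verdicts$not_gw_single)
  # strictness at the boundaries
  l4 <- apply_pleiotropy_filters(loc, c(PAD = 5e-3, LDL = 1e-4))
  expect_false(l4$verdicts$pleiotropy_pass)
  l5 <- apply_pleiotropy_filters(loc, c(PAD = 5e-8, LDL = 1e-4))
  expect_false(l5$verdicts$not_gw_single)
})

test_that("loci overlapping the HLA region are flagged", {
  res <- make_result("6", 28e6, 1e-10)
  loc <- apply_pleiotropy_filters(define_locus(res$key[1], res))
  expect_false(loc$verdicts$outside_hla)
  # window poking into the region from outside also counts
  res2 <- make_result("6", 24.5e6, 1e-10)
  loc2 <- apply_pleiotropy_filters(define_locus(res2$key[1], res2))
  expect_false(loc2$verdicts$outside_hla)
  res3 <- make_result("6", 40e6, 1e-10)
  loc3 <- apply_pleiotropy_filters(define_locus(res3$key[1], res3))
  expect_true(loc3$verdicts$outside_hla)
})

test_that("novelty filter screens members against trait-matched catalog entries", {
  res <- make_result("1", c(10e6, 10.4e6), c(1e-10, 1e-6),
                     c("sent", "memb"))
  loc <- define_locus(res$key[1], res)
  # catalog entry at the sentinel position for a scan trait: known
  cat1 <- data.frame(trait = "A", variant_id = "kx", chrom = "1",
                     pos = 10e6, stringsAsFactors = FALSE)
  expect_false(apply_novelty_filter(loc, cat1, res)$verdicts$novel_vs_catalog)
  # entry 600 kb from every member, no LD: novel
  cat2 <- data.frame(trait = "A", variant_id = "kx", chrom = "1",
                     pos = 11.05e6, stringsAsFactors = FALSE)
  expect_true(apply_novelty_filter(loc, cat2, res)$verdicts$novel_vs_catalog)
  # member (not sentinel) within 500 kb: known
  cat3 <- data.frame(trait = "A", variant_id = "kx", chrom = "1",
                     pos = 10.8e6, stringsAsFactors = FALSE)
  expect_false(apply_novelty_filter(loc, cat3, res)$verdicts$novel_vs_catalog)
  # same position but a trait outside the scan: still novel
  cat4 <- data.frame(trait = "T2D", variant_id = "kx", chrom = "1",
                     pos = 10e6, stringsAsFactors = FALSE)
  expect_true(apply_novelty_filter(loc, cat4, res)$verdicts$novel_vs_catalog)
  # LD above 0.2 with a member, far away: known
  cat5 <- data.frame(trait = "B", variant_id = "kx", chrom = "1",
                     pos = 90e6, stringsAsFactors = FALSE)
  ld <- ld_table("memb", "kx", 0.35)
  expect_false(
    apply_novelty_filter(loc, cat5, res, ld)$verdicts$novel_vs_catalog)
})

test_that("filters are pure and idempotent", {
  res <- make_result("1", 10e6, 1e-10)
  loc <- define_locus(res$key[1], res)
  l1 <- apply_pleiotropy_filters(loc)
  l2 <- apply_pleiotropy_filters(l1)
  expect_identical(l1$verdicts, l2$verdicts)
})

test_that("single-linkage locus merging is transitive and order-invariant", {
  df <- data.frame(chrom = c("1", "1", "1", "2"),
                   pos = c(1e6, 1.9e6, 2.8e6, 1e6),
                   p_multi = c(1e-10, 1e-9, 1e-8, 1e-12),
                   sentinel_id = c("a", "b", "c", "d"),
                   stringsAsFactors = FALSE)
  m <- merge_independent_loci(df)
  expect_equal(m$n_clusters, 2)  # chain 1-2-3 merges transitively
  set.seed(2)
  for (i in 1:5) {
    perm <- sample(nrow(df))
    mp <- merge_independent_loci(df[perm, ])
    expect_equal(mp$n_clusters, m$n_clusters)
    # same partition up to relabeling
    expect_equal(length(unique(paste(mp$cluster[order(perm)]))),
                 length(unique(m$cluster)))
    expect_true(all(table(mp$cluster) %in% table(m$cluster)))
  }
  # two sentinels 0.9 Mb apart merge; identical ids collapse
  df2 <- data.frame(chrom = "5", pos = c(1e6, 1.9e6), p_multi = c(1e-9, 1e-8),
                    sentinel_id = c("x", "y"), stringsAsFactors = FALSE)
  expect_equal(merge_independent_loci(df2)$n_clusters, 1)
  df3 <- data.frame(chrom = c("5", "7"), pos = c(1e6, 50e6),
                    p_multi = c(1e-9, 1e-8),
                    sentinel_id = c("x", "x"), stringsAsFactors = FALSE)
  expect_equal(merge_independent_loci(df3)$n_clusters, 1)
})

test_that("published sentinel table reproduces the reported locus counts", {
  tab <- reference_sentinels()
  expect_equal(nrow(tab), 31)
  m_all <- merge_independent_loci(
    data.frame(chrom = tab$chrom, pos = tab$pos, p_multi = tab$p_multi,
               sentinel_id = tab$sentinel, stringsAsFactors = FALSE))
  expect_equal(m_all$n_clusters, 25)
  ew <- tab[tab$p_multi < 4.3e-9, ]
  expect_equal(nrow(ew), 13)
  m_ew <- merge_independent_loci(
    data.frame(chrom = ew$chrom, pos = ew$pos, p_multi = ew$p_multi,
               sentinel_id = ew$sentinel, stringsAsFactors = FALSE))
  expect_equal(m_ew$n_clusters, 11)
})
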