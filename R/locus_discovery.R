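# Sentinel selection, locus definition, and the pleiotropy/novelty filter
# cascade that turns per-scan multivariate results into candidate loci.

#' Extended HLA/MHC exclusion region (GRCh37)
#'
#' Conventional extended-MHC bounds on chromosome 6, excluded from locus
#' discovery because its long-range LD defeats independent-signal logic.
#'
#' @return list with `chrom`, `start`, `end` (1-based inclusive).
#' @export
hla_region_grch37 <- function() {
  list(chrom = "6", start = 25000000L, end = 34000000L)
}

#' Read a BED region file as 1-based inclusive regions
#'
#' BED is 0-based half-open; rows come back converted to the 1-based
#' inclusive convention used everywhere else in the package.
#'
#' @param path BED file (chrom, start, end; no header).
#' @return data frame with `chrom`, `start`, `end`.
#' @export
read_bed_regions <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(chrom = as.character(tab[[1]]),
             start = as.integer(tab[[2]]) + 1L,
             end = as.integer(tab[[3]]),
             stringsAsFactors = FALSE)
}

#' Greedy sentinel selection
#'
#' Repeatedly takes the variant with the smallest multivariate p below the
#' threshold that is not already claimed by a previous sentinel's locus
#' (1 Mb window plus LD `r2 > r2_min`); ties are broken by (chrom, pos).
#'
#' @param result a `multitrait_result`.
#' @param p_threshold significance cutoff on `p_multi`.
#' @param ld an `ld_table` (optional; without it only the window rule
#'   claims variants).
#' @param window_bp claiming window around each sentinel (default 1 Mb).
#' @param r2_min LD threshold for claiming beyond the window.
#' @return character vector of sentinel variant keys in selection order.
#' @export
find_sentinels <- function(result, p_threshold, ld = NULL,
                           window_bp = 1e6, r2_min = 0.2) {
  sig <- which(result$p_multi < p_threshold)
  if (!length(sig)) return(character())
  ord <- sig[order(result$p_multi[sig], result$chrom[sig], result$pos[sig])]
  claimed <- rep(FALSE, nrow(result))
  sentinels <- character()
  for (i in ord) {
    if (claimed[i]) next
    sentinels <- c(sentinels, result$key[i])
    members <- locus_members(result, i, ld, window_bp, r2_min)
    claimed[members] <- TRUE
  }
  sentinels
}

# Row indices of a sentinel's locus members: same-chromosome variants within
# the window, plus any variant in LD above r2_min regardless of distance.
#' @noRd
locus_members <- function(result, sent_idx, ld, window_bp, r2_min) {
  same_chr <- result$chrom == result$chrom[sent_idx]
  inwin <- same_chr & abs(result$pos - result$pos[sent_idx]) <= window_bp
  if (!is.null(ld)) {
    r2 <- ld_r2(ld, result$variant_id, result$variant_id[sent_idx])
    inwin <- inwin | r2 > r2_min
  }
  which(inwin)
}

#' Define the locus around a sentinel variant
#'
#' An independent locus is the genomic region holding all variants within
#' `window_bp` of the sentinel plus any variant in LD (`r2 > r2_min`) with
#' it, regardless of distance.
#'
#' @param sentinel_key variant key of the sentinel (must be in `result`).
#' @param result a `multitrait_result`.
#' @param ld an `ld_table` or `NULL`.
#' @param window_bp window half-width in bp (default 1 Mb).
#' @param r2_min LD membership threshold (strict `>`).
#' @return a `locus`: list with `scan`, `sentinel` (the result row),
#'   `members` (variant keys), `window`, `verdicts`, `tier`.
#' @export
define_locus <- function(sentinel_key, result, ld = NULL,
                         window_bp = 1e6, r2_min = 0.2) {
  i <- match(sentinel_key, result$key)
  if (is.na(i)) stop("sentinel not present in result", call. = FALSE)
  idx <- locus_members(result, i, ld, window_bp, r2_min)
  structure(
    list(scan = attr(result, "scan"),
         sentinel = result[i, , drop = FALSE],
         members = result$key[idx],
         window = list(chrom = result$chrom[i],
                       start = max(1, result$pos[i] - window_bp),
                       end = result$pos[i] + window_bp),
         verdicts = list(), tier = "none"),
    class = "locus"
  )
}

#' Pleiotropy and HLA filters on a locus
#'
#' A locus is plausibly pleiotropic when its sentinel is at least nominally
#' associated with every scanned trait (`p < nominal_p`) while not
#' genome-wide significant for any single trait (`p > gw_p`), and lies
#' outside the HLA region. Inequalities are strict.
#'
#' @param locus a `locus`.
#' @param single_trait_p named vector of per-trait sentinel p-values, one
#'   per scan trait (defaults to the `p.*` columns stored on the sentinel).
#' @param nominal_p nominal association cutoff (default `5e-3`).
#' @param gw_p single-trait genome-wide cutoff (default `5e-8`).
#' @param hla exclusion region (list chrom/start/end).
#' @return the locus with verdicts `pleiotropy_pass`, `not_gw_single`,
#'   `outside_hla` filled in.
#' @export
apply_pleiotropy_filters <- function(locus, single_trait_p = NULL,
                                     nominal_p = 5e-3, gw_p = 5e-8,
                                     hla = hla_region_grch37()) {
  traits <- locus$scan$traits
  if (is.null(single_trait_p)) {
    cols <- paste0("p.", traits)
    if (!all(cols %in% names(locus$sentinel))) {
      stop("missing per-trait p for trait(s): ",
           paste(traits[!cols %in% names(locus$sentinel)], collapse = ", "),
           call. = FALSE)
    }
    single_trait_p <- stats::setNames(
      as.numeric(locus$sentinel[1, cols]), traits)
  }
  if (!all(traits %in% names(single_trait_p)) ||
      any(is.na(single_trait_p[traits]))) {
    stop("missing per-trait p for trait(s): ",
         paste(setdiff(traits, names(single_trait_p)), collapse = ", "),
         call. = FALSE)
  }
  p <- single_trait_p[traits]
  w <- locus$window
  in_hla <- identical(as.character(w$chrom), as.character(hla$chrom)) &&
    w$start <= hla$end && w$end >= hla$start
  locus$verdicts$pleiotropy_pass <- all(p < nominal_p)
  locus$verdicts$not_gw_single <- all(p > gw_p)
  locus$verdicts$outside_hla <- !in_hla
  locus
}

#' Novelty filter against a known-association catalog
#'
#' A locus is novel when no member variant lies within `proximity_bp` of,
#' or in LD (`r2 > r2_min`) with, any catalog entry reported for one of the
#' scan's traits. Trait matching is exact-string.
#'
#' @param locus a `locus`.
#' @param catalog data frame from [read_catalog()].
#' @param result the `multitrait_result` the locus came from (supplies
#'   member positions).
#' @param ld an `ld_table` or `NULL`.
#' @param proximity_bp proximity radius (default 500 kb).
#' @param r2_min LD threshold (strict `>`).
#' @return the locus with verdict `novel_vs_catalog` filled in.
#' @export
apply_novelty_filter <- function(locus, catalog, result, ld = NULL,
                                 proximity_bp = 5e5, r2_min = 0.2) {
  hits <- catalog[catalog$trait %in% locus$scan$traits, , drop = FALSE]
  if (!nrow(hits)) {
    locus$verdicts$novel_vs_catalog <- TRUE
    return(locus)
  }
  mi <- match(locus$members, result$key)
  mchrom <- result$chrom[mi]; mpos <- result$pos[mi]
  mid <- result$variant_id[mi]
  known <- FALSE
  for (h in seq_len(nrow(hits))) {
    near <- mchrom == hits$chrom[h] &
      abs(mpos - hits$pos[h]) <= proximity_bp
    if (any(near)) { known <- TRUE; break }
    if (!is.null(ld)) {
      if (any(ld_r2(ld, mid, hits$variant_id[h]) > r2_min &
              mid != hits$variant_id[h] |
              mid == hits$variant_id[h])) { known <- TRUE; break }
    }
  }
  locus$verdicts$novel_vs_catalog <- !known
  locus
}

#' Merge loci across scans into independent clusters
#'
#' Single-linkage clustering of sentinels: identical sentinel variants
#' collapse first, then sentinels on the same chromosome within
#' `distance_bp` of each other merge transitively. Each cluster's
#' representative is its lowest-`p_multi` locus (ties by chrom, pos).
#'
#' @param loci list of `locus` objects, or a data frame with columns
#'   `chrom`, `pos` (and optionally `p_multi`, `sentinel_id`).
#' @param distance_bp merge radius (loci further apart than this are
#'   independent; default 1 Mb).
#' @return list with `cluster` (integer id per input locus, in input
#'   order) and `representatives` (indices of cluster representatives).
#' @export
merge_independent_loci <- function(loci, distance_bp = 1e6) {
  if (is.data.frame(loci)) {
    df <- loci
    if (is.null(df$p_multi)) df$p_multi <- NA_real_
    if (is.null(df$sentinel_id)) df$sentinel_id <- paste0("s", seq_len(nrow(df)))
  } else {
    df <- do.call(rbind, lapply(loci, function(l) {
      data.frame(chrom = l$sentinel$chrom, pos = l$sentinel$pos,
                 p_multi = l$sentinel$p_multi,
                 sentinel_id = l$sentinel$variant_id,
                 stringsAsFactors = FALSE)
    }))
  }
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (df$sentinel_id[i] == df$sentinel_id[j] ||
          (df$chrom[i] == df$chrom[j] &&
           abs(df$pos[i] - df$pos[j]) <= distance_bp)) {
        union_(i, j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  cluster <- match(roots, sort(unique(roots)))
  reps <- vapply(sort(unique(cluster)), function(cl) {
    idx <- which(cluster == cl)
    idx[order(df$p_multi[idx], df$chrom[idx], df$pos[idx])][1]
  }, integer(1))
  list(cluster = cluster, representatives = reps,
       n_clusters = length(reps))
}

#' @export
print.locus <- function(x, ...) {
  v <- x$verdicts
  cat("<locus> scan ", x$scan$label, ", sentinel ",
      x$sentinel$variant_id, " (", x$sentinel$chrom, ":", x$sentinel$pos,
      "), ", length(x$members), " members, tier ", x$tier,
      if (length(v)) paste0("\n  verdicts: ",
                            paste(names(v), unlist(v), sep = "=",
                                  collapse = ", ")) else "",
      "\n", sep = "")
  invisible(x)
}
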