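# Deletion recurrence screen: shortlist homology-mediated deletions,
# identify recurrence-indicating SNPs (both SNP alleles observed with and
# without the deletion), and cluster local SNP haplotypes to ask whether
# deletion carriers appear on distinct haplotype backgrounds.

#' Construct a haplotype panel
#'
#' @param snp_positions Integer positions (bp) of the SNP columns.
#' @param matrix Haplotype-by-SNP 0/1 matrix.
#' @param del_state 0/1 vector: focal deletion carried per haplotype.
#' @param del_start,del_end Deletion interval (0-based half-open).
#' @return `sv_hap_panel` list; `maf` is computed per SNP.
#' @export
hap_panel <- function(snp_positions, matrix, del_state, del_start, del_end) {
  stopifnot(ncol(matrix) == length(snp_positions),
            nrow(matrix) == length(del_state),
            all(matrix %in% c(0L, 1L)), all(del_state %in% c(0L, 1L)))
  f <- colMeans(matrix)
  structure(list(snp_positions = as.integer(snp_positions),
                 matrix = matrix, del_state = as.integer(del_state),
                 del_start = as.integer(del_start),
                 del_end = as.integer(del_end),
                 maf = pmin(f, 1 - f)),
            class = "sv_hap_panel")
}

#' Shortlist deletions for the recurrence screen
#'
#' Retains deletions passing all filters: length below `max_len`; flanking
#' homology within `hom_range`; allele frequency within `af_range`;
#' Hardy-Weinberg and Mendelian screens passed (when provided); phased.
#' Records missing a needed annotation are excluded with the missing field
#' named.
#'
#' @param dels data.frame with columns `id`, `svlen`, `hom_len`, `af`,
#'   `phased`, and optional logical `hwe_ok`, `mendel_ok`.
#' @param max_len Maximum deletion length (exclusive, bp).
#' @param hom_range Flanking homology bounds (bp, inclusive).
#' @param af_range Allele-frequency band (inclusive).
#' @return List with `kept` and `excluded` (the latter with a `reason`
#'   column).
#' @export
shortlist_candidates <- function(dels, max_len = 5000,
                                 hom_range = c(200, 9000),
                                 af_range = c(0.40, 0.60)) {
  reason <- rep(NA_character_, nrow(dels))
  need <- c("svlen", "hom_len", "af", "phased")
  for (i in seq_len(nrow(dels))) {
    missing <- need[vapply(need, function(f) is.na(dels[[f]][i]), logical(1))]
    if (length(missing)) {
      reason[i] <- paste0("missing:", missing[1]); next
    }
    if (dels$svlen[i] >= max_len) { reason[i] <- "length"; next }
    if (dels$hom_len[i] < hom_range[1] || dels$hom_len[i] > hom_range[2]) {
      reason[i] <- "homology"; next
    }
    if (dels$af[i] < af_range[1] || dels$af[i] > af_range[2]) {
      reason[i] <- "allele_frequency"; next
    }
    if (!is.null(dels$hwe_ok) && !isTRUE(dels$hwe_ok[i])) {
      reason[i] <- "hardy_weinberg"; next
    }
    if (!is.null(dels$mendel_ok) && !isTRUE(dels$mendel_ok[i])) {
      reason[i] <- "mendelian"; next
    }
    if (!isTRUE(dels$phased[i])) { reason[i] <- "unphased"; next }
  }
  excluded <- dels[!is.na(reason), , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[!is.na(reason)]
  list(kept = dels[is.na(reason), , drop = FALSE], excluded = excluded)
}

#' Recurrence-indicating SNPs around a deletion
#'
#' A SNP within a `window` bp window centred on the deletion midpoint and
#' with minor allele frequency at least `min_maf` qualifies when haplotypes
#' with all four combinations of SNP allele and deletion state are observed
#' at least once. SNPs inside the deletion are skipped.
#'
#' @param panel `sv_hap_panel`.
#' @param window Window width (bp).
#' @param min_maf Minimum minor allele frequency.
#' @return data.frame with `position` and `side` ("upstream"/"downstream").
#' @export
recurrence_snps <- function(panel, window = 20000, min_maf = 0.10) {
  mid <- (panel$del_start + panel$del_end) / 2
  pos <- panel$snp_positions
  in_win <- pos >= mid - window / 2 & pos <= mid + window / 2
  outside <- pos < panel$del_start | pos >= panel$del_end
  cand <- which(in_win & outside & panel$maf >= min_maf)
  hit <- logical(length(cand))
  d <- panel$del_state
  for (k in seq_along(cand)) {
    a <- panel$matrix[, cand[k]]
    hit[k] <- any(a == 0 & d == 0) && any(a == 0 & d == 1) &&
      any(a == 1 & d == 0) && any(a == 1 & d == 1)
  }
  q <- cand[hit]
  data.frame(position = pos[q],
             side = ifelse(pos[q] < panel$del_start, "upstream", "downstream"),
             stringsAsFactors = FALSE)
}

#' Centroid hierarchical clustering of local SNP haplotypes
#'
#' Haplotypes are clustered on the SNP columns within a `window` bp window
#' centred on the deletion, using centroid linkage on the normalized Hamming
#' distance (mean allele mismatch, the squared Euclidean distance of binary
#' vectors scaled by SNP count). Flat groups are cut at `cut_height`
#' (fraction of window SNPs differing) unless `k` is given.
#'
#' @param panel `sv_hap_panel`.
#' @param window Window width (bp).
#' @param cut_height Dissimilarity cut for flat groups.
#' @param k Optional fixed number of groups (overrides `cut_height`).
#' @return List with `tree` (hclust), `groups` (integer vector) and
#'   `n_snps`.
#' @export
cluster_haplotypes <- function(panel, window = 100000, cut_height = 0.2,
                               k = NULL) {
  mid <- (panel$del_start + panel$del_end) / 2
  keep <- panel$snp_positions >= mid - window / 2 &
    panel$snp_positions <= mid + window / 2
  x <- panel$matrix[, keep, drop = FALSE]
  n <- nrow(x)
  if (n < 2) {
    return(list(tree = NULL, groups = rep(1L, n), n_snps = ncol(x)))
  }
  if (ncol(x) == 0 || all(apply(x, 2, function(c) length(unique(c)) == 1))) {
    return(list(tree = NULL, groups = rep(1L, n), n_snps = ncol(x)))
  }
  # squared Euclidean distance of 0/1 rows equals the Hamming count
  d2 <- as.matrix(stats::dist(x, method = "euclidean"))^2 / ncol(x)
  tree <- stats::hclust(stats::as.dist(d2), method = "centroid")
  groups <- if (!is.null(k)) stats::cutree(tree, k = k) else
    cut_tree_height(tree, cut_height)
  list(tree = tree, groups = as.integer(groups), n_snps = ncol(x))
}

# Flat groups at a height cut that tolerates the inversions centroid
# linkage can produce: haplotypes are in one group when they are joined by
# merges at height <= h (union-find over the merge list).
cut_tree_height <- function(tree, h) {
  n <- length(tree$order)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  node_members <- vector("list", nrow(tree$merge))
  for (m in seq_len(nrow(tree$merge))) {
    kids <- tree$merge[m, ]
    mem <- unlist(lapply(kids, function(k) {
      if (k < 0) -k else node_members[[k]]
    }))
    node_members[[m]] <- mem
    if (tree$height[m] <= h) {
      r <- find(mem[1])
      for (x in mem[-1]) {
        rx <- find(x)
        if (rx != r) parent[rx] <- r
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Assess recurrence of a deletion on a haplotype panel
#'
#' The verdict is `supported` when qualifying recurrence-indicating SNPs
#' exist on both sides of the deletion and deletion carriers occur in at
#' least two distinct haplotype groups. An inspection table (consensus
#' haplotype, size and deletion frequency per cluster) is emitted for manual
#' audit.
#'
#' @param panel `sv_hap_panel`.
#' @param snps Optional precomputed [recurrence_snps()] table.
#' @param clusters Optional precomputed [cluster_haplotypes()] result.
#' @param ... Passed to the two underlying operations.
#' @return `sv_recurrence_report` list: `verdict`, `recurrence_snps`,
#'   `groups`, `cluster_table`.
#' @export
assess_recurrence <- function(panel, snps = NULL, clusters = NULL, ...) {
  if (is.null(snps)) snps <- recurrence_snps(panel)
  if (is.null(clusters)) clusters <- cluster_haplotypes(panel)
  both_sides <- all(c("upstream", "downstream") %in% snps$side)
  carrier_groups <- unique(clusters$groups[panel$del_state == 1])
  supported <- both_sides && length(carrier_groups) >= 2
  tab <- do.call(rbind, lapply(sort(unique(clusters$groups)), function(g) {
    idx <- clusters$groups == g
    data.frame(
      group = g, n_haplotypes = sum(idx),
      del_frequency = mean(panel$del_state[idx]),
      consensus = paste(round(colMeans(panel$matrix[idx, , drop = FALSE])),
                        collapse = ""),
      stringsAsFactors = FALSE
    )
  }))
  structure(list(
    verdict = if (supported) "supported" else "unsupported",
    recurrence_snps = snps, groups = clusters$groups, cluster_table = tab
  ), class = "sv_recurrence_report")
}
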