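# Callset duplicate marking and callset-to-callset matching. Both operations
# evaluate the same four pairwise rules (breakpoint offset, size ratio,
# allele divergence, shared carriers) at different thresholds.

#' Normalized global-alignment divergence of two allele sequences
#'
#' Levenshtein distance (global alignment with unit mismatch and gap costs)
#' normalized by the longer allele length.
#'
#' @param a,b DNA strings.
#' @return Divergence in \[0, 1\].
#' @export
allele_divergence <- function(a, b) {
  if (nchar(a) == 0 && nchar(b) == 0) return(0)
  as.numeric(adist(a, b)) / max(nchar(a), nchar(b))
}

# Pairwise duplicate/match rule. Breakpoint offset is the larger of the
# start and end offsets. Size ratio is min/max of svlen. Carrier sharing is
# |intersection| / smaller carrier set; records without genotypes satisfy
# the carrier criterion by convention (relaxation recorded by the caller).
sv_pair_rules <- function(r1, r2, max_offset, min_size_ratio, max_divergence,
                          min_carrier_frac = NULL, ratio_strict = FALSE) {
  if (is.na(r1$svtype) || is.na(r2$svtype)) return(FALSE)
  if (!identical(r1$chrom, r2$chrom) || !identical(r1$svtype, r2$svtype)) {
    return(FALSE)
  }
  offset <- max(abs(r1$start - r2$start), abs(r1$end - r2$end))
  if (offset > max_offset) return(FALSE)
  ratio <- min(r1$svlen, r2$svlen) / max(r1$svlen, r2$svlen, 1L)
  if (ratio_strict) {
    if (ratio <= min_size_ratio) return(FALSE)
  } else if (ratio < min_size_ratio) {
    return(FALSE)
  }
  if (allele_divergence(sv_allele_seq(r1), sv_allele_seq(r2)) > max_divergence) {
    return(FALSE)
  }
  if (!is.null(min_carrier_frac)) {
    g1 <- if (is.null(r1$gt)) NULL else r1$gt[[1]]
    g2 <- if (is.null(r2$gt)) NULL else r2$gt[[1]]
    if (!is.null(g1) && !is.null(g2) && length(g1) && length(g2)) {
      c1 <- gt_carriers(g1); c2 <- gt_carriers(g2)
      denom <- min(length(c1), length(c2))
      shared <- if (denom == 0) 0 else length(intersect(c1, c2)) / denom
      if (shared < min_carrier_frac) return(FALSE)
    }
  }
  TRUE
}

#' Mark duplicate SV sites within a callset
#'
#' Two records are duplicates when all four criteria hold: breakpoint offset
#' at most `max_offset`, SV size ratio greater than `min_size_ratio`, allele
#' divergence at most `max_divergence` and a fraction of shared carriers of
#' at least `min_carrier_frac`. Duplicate groups are the transitive closure
#' of the pairwise relation; within each group exactly one representative is
#' retained (smallest start, then longest, then lexicographically smallest
#' id). Records lacking genotypes satisfy the carrier criterion by
#' convention; this relaxation is recorded in the `carrier_relaxed` column.
#'
#' @param records `sv_records` table.
#' @param max_offset Maximum breakpoint offset in bp.
#' @param min_size_ratio Size ratio must exceed this value.
#' @param max_divergence Maximum allele divergence.
#' @param min_carrier_frac Minimum fraction of shared carriers.
#' @return The records with added columns `dup_group`, `duplicate` (TRUE for
#'   non-representative members) and `carrier_relaxed`.
#' @export
mark_duplicate_sites <- function(records, max_offset = 500,
                                 min_size_ratio = 0.5, max_divergence = 0.30,
                                 min_carrier_frac = 0.10) {
  n <- nrow(records)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  relaxed <- logical(n)
  if (n > 1) {
    o <- order(records$chrom, records$svtype, records$start)
    for (a in seq_len(n - 1L)) {
      i <- o[a]
      for (b in (a + 1L):n) {
        j <- o[b]
        if (!identical(records$chrom[j], records$chrom[i]) ||
            !identical(records$svtype[j], records$svtype[i])) break
        if (records$start[j] - records$start[i] > max_offset) break
        if (sv_pair_rules(records[i, ], records[j, ], max_offset,
                          min_size_ratio, max_divergence, min_carrier_frac,
                          ratio_strict = TRUE)) {
          gi <- is.null(records$gt) || is.null(records$gt[[i]]) ||
            length(records$gt[[i]]) == 0
          gj <- is.null(records$gt) || is.null(records$gt[[j]]) ||
            length(records$gt[[j]]) == 0
          if (gi || gj) { relaxed[i] <- relaxed[i] || gi; relaxed[j] <- relaxed[j] || gj }
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  grp <- vapply(seq_len(n), find, integer(1))
  grp <- match(grp, unique(grp))
  dup <- logical(n)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) == 1) next
    o <- idx[order(records$start[idx], -records$svlen[idx], records$id[idx])]
    dup[setdiff(idx, o[1])] <- TRUE
  }
  records$dup_group <- grp
  records$duplicate <- dup
  records$carrier_relaxed <- relaxed
  records
}

#' Match a base callset against a comparison callset
#'
#' A base record matches a comparison record of the same type when the
#' breakpoint offset is at most `max_offset`, the size ratio is at least
#' `min_size_ratio` and the allele divergence is at most `max_divergence`.
#' All links are preserved (one-to-many matches are not collapsed).
#'
#' @param base,comp `sv_records` tables on the same reference.
#' @param max_offset Maximum breakpoint offset in bp.
#' @param min_size_ratio Minimum size ratio (inclusive).
#' @param max_divergence Maximum allele divergence (inclusive).
#' @return List with `base` (records plus `matched` and `n_matches` columns)
#'   and `links` (data.frame of base_id / comp_id pairs).
#' @export
match_callsets <- function(base, comp, max_offset = 50, min_size_ratio = 0.8,
                           max_divergence = 0.10) {
  links <- list()
  matched <- logical(nrow(base))
  nmatch <- integer(nrow(base))
  if (nrow(base) && nrow(comp)) {
    for (i in seq_len(nrow(base))) {
      cand <- which(comp$chrom == base$chrom[i] &
                      comp$svtype == base$svtype[i] &
                      abs(comp$start - base$start[i]) <= max_offset)
      for (j in cand) {
        if (sv_pair_rules(base[i, ], comp[j, ], max_offset, min_size_ratio,
                          max_divergence, min_carrier_frac = NULL,
                          ratio_strict = FALSE)) {
          links[[length(links) + 1L]] <-
            data.frame(base_id = base$id[i], comp_id = comp$id[j],
                       stringsAsFactors = FALSE)
          matched[i] <- TRUE
          nmatch[i] <- nmatch[i] + 1L
        }
      }
    }
  }
  base$matched <- matched
  base$n_matches <- nmatch
  list(
    base = base,
    links = if (length(links)) do.call(rbind, links) else
      data.frame(base_id = character(0), comp_id = character(0),
                 stringsAsFactors = FALSE)
  )
}
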