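# Source-element atlas: cluster traced transductions into progenitor
# regions, assign full-length progenitor elements, and test each locus for
# a 5'/3' transduction bias.

#' Cluster transduction source alignments into source regions
#'
#' Source intervals are padded by `buffer` bp on both sides and merged
#' transitively; each transduction is assigned to exactly one region.
#'
#' @param transductions data.frame with columns `sv_id`, `side`
#'   ("5p"/"3p"/"orphan"), `chrom`, `start`, `end` (0-based source
#'   alignment).
#' @param buffer Padding (bp).
#' @return List with `regions` (data.frame: region_id, chrom, start, end —
#'   merged padded extent clipped at 0) and `assignment` (region_id per
#'   input row).
#' @export
cluster_sources <- function(transductions, buffer = 10000) {
  if (nrow(transductions) == 0) {
    return(list(regions = data.frame(region_id = integer(0),
                                     chrom = character(0), start = integer(0),
                                     end = integer(0)),
                assignment = integer(0)))
  }
  gr <- GenomicRanges::GRanges(
    transductions$chrom,
    IRanges::IRanges(start = pmax(0L, transductions$start - buffer) + 1L,
                     end = transductions$end + buffer)
  )
  red <- GenomicRanges::reduce(gr)
  ov <- GenomicRanges::findOverlaps(gr, red, select = "first")
  regions <- data.frame(
    region_id = seq_along(red),
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    stringsAsFactors = FALSE
  )
  list(regions = regions, assignment = as.integer(ov))
}

#' Assign a full-length progenitor element to a source region
#'
#' The region is intersected with a database of full-length elements
#' (reference annotations plus non-reference full-length insertions: L1
#' longer than 5.9 kb, SVA longer than 1 kb). With several candidates the
#' element nearest to the centroid of the member source alignments wins
#' (ties logged via the `tie` flag).
#'
#' @param region One row of the regions table from [cluster_sources()].
#' @param full_length_db data.frame (chrom, start, end, class, subfamily,
#'   orientation, in_reference).
#' @param centroid Optional centroid (bp) of member alignment midpoints;
#'   defaults to the region midpoint.
#' @param l1_min,sva_min Full-length thresholds (bp).
#' @return NULL (progenitor unknown) or the chosen db row with `distance`
#'   and `tie` added.
#' @export
assign_progenitor <- function(region, full_length_db, centroid = NULL,
                              l1_min = 5900, sva_min = 1000) {
  db <- full_length_db
  len <- db$end - db$start
  full <- (db$class == "L1" & len > l1_min) | (db$class == "SVA" & len > sva_min)
  db <- db[full & db$chrom == region$chrom &
             db$end > region$start & db$start < region$end, , drop = FALSE]
  if (nrow(db) == 0) return(NULL)
  if (is.null(centroid)) centroid <- (region$start + region$end) / 2
  mid <- (db$start + db$end) / 2
  d <- abs(mid - centroid)
  best <- which(d == min(d))
  out <- db[best[1], , drop = FALSE]
  out$distance <- d[best[1]]
  out$tie <- length(best) > 1
  out
}

#' Two-tailed binomial 5'/3' bias test over source loci
#'
#' Loci with fewer than `min_n` non-orphan transductions are untested and
#' excluded from the Benjamini-Hochberg family; tested loci get an exact
#' two-tailed binomial p-value against `null_p` and a bias label toward the
#' majority side when the adjusted p-value is below `alpha`.
#'
#' @param loci data.frame with columns `n_5p`, `n_3p` (and anything else,
#'   preserved).
#' @param null_p Null proportion of 5' transductions.
#' @param min_n Minimum non-orphan transductions for testing.
#' @param alpha Adjusted significance level.
#' @return `loci` with `p_value`, `p_adjusted` and `bias` ("5p", "3p",
#'   "none", "untested") columns.
#' @export
bias_test <- function(loci, null_p = 0.5, min_n = 5, alpha = 0.05) {
  n <- loci$n_5p + loci$n_3p
  tested <- n >= min_n
  p <- rep(NA_real_, nrow(loci))
  for (i in which(tested)) {
    p[i] <- stats::binom.test(loci$n_5p[i], n[i], p = null_p,
                              alternative = "two.sided")$p.value
  }
  padj <- rep(NA_real_, nrow(loci))
  padj[tested] <- stats::p.adjust(p[tested], method = "BH")
  bias <- ifelse(!tested, "untested", "none")
  sig <- tested & !is.na(padj) & padj < alpha
  bias[sig] <- ifelse(loci$n_5p[sig] > loci$n_3p[sig], "5p", "3p")
  loci$p_value <- p
  loci$p_adjusted <- padj
  loci$bias <- bias
  loci
}

#' Build the transduction source-element atlas
#'
#' Clusters traced transductions into source regions, counts 5'/3'/orphan
#' events per region, assigns full-length progenitors and runs the bias
#' test.
#'
#' @param transductions data.frame as for [cluster_sources()].
#' @param full_length_db Optional full-length element database.
#' @param buffer Clustering buffer (bp).
#' @param ... Passed to [bias_test()].
#' @return Source-locus table: region coordinates, element class/subfamily/
#'   orientation (NA when unknown), `n_5p`, `n_3p`, `n_orphan`, `p_value`,
#'   `p_adjusted`, `bias`.
#' @export
build_source_atlas <- function(transductions, full_length_db = NULL,
                               buffer = 10000, ...) {
  cl <- cluster_sources(transductions, buffer = buffer)
  if (nrow(cl$regions) == 0) return(cl$regions)
  loci <- cl$regions
  loci$n_5p <- 0L; loci$n_3p <- 0L; loci$n_orphan <- 0L
  loci$element_class <- NA_character_
  loci$element_subfamily <- NA_character_
  loci$element_orientation <- NA_character_
  for (g in seq_len(nrow(loci))) {
    idx <- which(cl$assignment == g)
    loci$n_5p[g] <- sum(transductions$side[idx] == "5p")
    loci$n_3p[g] <- sum(transductions$side[idx] == "3p")
    loci$n_orphan[g] <- sum(transductions$side[idx] == "orphan")
    if (!is.null(full_length_db)) {
      centroid <- mean((transductions$start[idx] + transductions$end[idx]) / 2)
      el <- assign_progenitor(loci[g, ], full_length_db, centroid = centroid)
      if (!is.null(el)) {
        loci$element_class[g] <- el$class
        loci$element_subfamily[g] <- el$subfamily
        loci$element_orientation[g] <- el$orientation
      }
    }
  }
  bias_test(loci, ...)
}
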