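# 3' transduction detection: a second poly(A) tract inside the trimmed,
# forward-oriented body splits it into element core + transduced segment.
# The segment is traced to its source locus by local alignment against the
# reference genome.

# Trace a candidate transduced segment against the genome. Returns NULL when
# the aligned fraction is below threshold, otherwise a list with the source
# interval (merged span of chained hits on the dominant contig) and stats.
trace_segment <- function(seg, genome, min_aligned_frac = 0.8,
                          min_identity = 0.8, seed_word = 15,
                          min_uniqueness = 10) {
  if (is.null(genome) || nchar(seg) < seed_word) {
    return(list(traced = FALSE, reason = "untraceable", source = NULL,
                aligned_fraction = NA_real_))
  }
  hits <- suppressWarnings(
    local_hits(seg, genome, min_identity = min_identity,
               seed_word = seed_word, min_uniqueness = min_uniqueness)
  )
  if (nrow(hits) == 0) {
    return(list(traced = FALSE, reason = "no_hits", source = NULL,
                aligned_fraction = 0))
  }
  chain <- chain_best(hits, nchar(seg))
  frac <- chain$covered_bases / nchar(seg)
  if (frac < min_aligned_frac) {
    return(list(traced = FALSE, reason = "aligned_fraction", source = NULL,
                aligned_fraction = frac))
  }
  ch <- chain$hits
  dom <- names(sort(table(ch$target), decreasing = TRUE))[1]
  chd <- ch[ch$target == dom, , drop = FALSE]
  list(
    traced = TRUE, reason = NULL,
    source = list(chrom = dom, start = min(chd$target_start),
                  end = max(chd$target_end),
                  strand = names(sort(table(chd$strand), decreasing = TRUE))[1]),
    aligned_fraction = frac
  )
}

#' Detect a 3' transduction in a trimmed insert body
#'
#' Searches the forward-oriented body (outer tail already trimmed) for a
#' second qualifying poly(A) tract. When found, the sequence 3' of that
#' tract is the candidate transduced segment; it is traced against the
#' genome and accepted only when at least `min_aligned_frac` of it aligns.
#' A failed trace demotes the insert to a solo candidate (the body is
#' returned unsplit); a segment too short to trace is recorded as a
#' transduction with no source.
#'
#' @param body Forward-oriented insert body.
#' @param genome Named character vector of contigs (NULL skips tracing).
#' @param min_aligned_frac Minimum aligned fraction of the transduced
#'   segment.
#' @param min_len,min_purity Internal poly(A) tract thresholds.
#' @param min_core Minimum element core length 5' of the tract (bp).
#' @param min_seg Minimum transduced segment length (bp).
#' @param seed_word,min_uniqueness Alignment parameters for tracing.
#' @return List with `core` (sequence used for decomposition), and
#'   `transduction` (NULL or list with `side`, `sequence`,
#'   `aligned_fraction`, `source`).
#' @export
detect_transductions <- function(body, genome = NULL, min_aligned_frac = 0.8,
                                 min_len = 10, min_purity = 0.90,
                                 min_core = 50, min_seg = 20,
                                 seed_word = 15, min_uniqueness = 10) {
  n <- nchar(body)
  tracts <- poly_tracts(body, "A", min_len = min_len, min_purity = min_purity)
  cand <- tracts[tracts$start >= min_core & (n - tracts$end) >= min_seg, ,
                 drop = FALSE]
  if (nrow(cand) == 0) {
    return(list(core = body, transduction = NULL))
  }
  tr <- cand[1, ]  # leftmost qualifying tract
  core <- substr(body, 1L, tr$start)
  seg <- substr(body, tr$end + 1L, n)
  trace <- trace_segment(seg, genome, min_aligned_frac = min_aligned_frac,
                         seed_word = seed_word,
                         min_uniqueness = min_uniqueness)
  if (!trace$traced && identical(trace$reason, "untraceable")) {
    return(list(core = core, transduction = list(
      side = "3p", sequence = seg, aligned_fraction = NA_real_, source = NULL
    )))
  }
  if (!trace$traced) {
    # filtered: demote to solo candidate, keep the body unsplit
    return(list(core = body, transduction = NULL))
  }
  list(core = core, transduction = list(
    side = "3p", sequence = seg, aligned_fraction = trace$aligned_fraction,
    source = trace$source
  ))
}
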