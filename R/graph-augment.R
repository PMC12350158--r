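# Pseudo-haplotype construction for pangenome graph augmentation: mask
# centromeres, partition the callset into non-overlapping groups, implant
# each group into the reference, and account for novel bubbles. Graph
# insertion itself is delegated to an external graph builder.

#' Mask genome regions with Ns
#'
#' @param genome Genome (named character vector).
#' @param mask data.frame (chrom, start, end), 0-based half-open.
#' @return The genome with masked bases replaced by N (lengths unchanged).
#' @export
mask_regions <- function(genome, mask) {
  for (i in seq_len(nrow(mask))) {
    chrom <- mask$chrom[i]
    if (!chrom %in% names(genome)) {
      stop("mask contig not in genome: ", chrom)
    }
    n <- nchar(genome[[chrom]])
    if (mask$start[i] < 0 || mask$end[i] > n || mask$start[i] > mask$end[i]) {
      stop(sprintf("mask interval out of bounds: %s:%d-%d", chrom,
                   mask$start[i], mask$end[i]))
    }
    if (mask$end[i] > mask$start[i]) {
      substr(genome[[chrom]], mask$start[i] + 1L, mask$end[i]) <-
        strrep("N", mask$end[i] - mask$start[i])
    }
  }
  genome
}

#' Drop records intersecting masked regions
#'
#' @param records `sv_records` table.
#' @param mask data.frame (chrom, start, end).
#' @return List with `kept` and `dropped` record tables.
#' @export
filter_masked_records <- function(records, mask) {
  drop <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    m <- mask[mask$chrom == records$chrom[i], , drop = FALSE]
    if (nrow(m) == 0) next
    drop[i] <- any(pmin(records$end[i], m$end) >
                     pmax(records$start[i], m$start))
  }
  list(kept = records[!drop, , drop = FALSE],
       dropped = records[drop, , drop = FALSE])
}

#' Partition a callset into non-overlapping groups
#'
#' Greedy first-fit interval partitioning over records sorted by (chrom,
#' start): each record goes into the lowest-index group where it does not
#' overlap the previously placed record on its contig. Deletions and complex
#' records occupy their REF span; insertions occupy a 1-bp point so two
#' insertions at the same position land in different groups. The number of
#' groups equals the maximum overlap depth of the input intervals.
#'
#' @param records `sv_records` table.
#' @return `records` with a `group_id` column.
#' @export
partition_nonoverlapping <- function(records) {
  o <- order(records$chrom, records$start, records$end)
  records <- records[o, , drop = FALSE]
  occ_start <- ifelse(records$svtype == "INS", records$start,
                      records$start)
  occ_end <- ifelse(records$svtype == "INS", records$start + 1L, records$end)
  group <- integer(nrow(records))
  last_end <- list()  # per group: named vector chrom -> last occupied end
  for (i in seq_len(nrow(records))) {
    placed <- FALSE
    for (g in seq_along(last_end)) {
      le <- last_end[[g]][[records$chrom[i]]]
      if (is.null(le) || le <= occ_start[i]) {
        group[i] <- g
        last_end[[g]][[records$chrom[i]]] <- occ_end[i]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      g <- length(last_end) + 1L
      last_end[[g]] <- setNames(list(occ_end[i]), records$chrom[i])
      group[i] <- g
    }
  }
  records$group_id <- group
  records
}

#' Implant one non-overlapping group into the reference
#'
#' Alleles are applied right-to-left per contig so earlier coordinates stay
#' valid; a REF mismatch at any implant site is an error (guards stale
#' coordinates). A coordinate map (per-variant length shifts) is emitted.
#'
#' @param genome Genome.
#' @param group `sv_records` rows, pairwise non-overlapping per contig.
#' @param group_id Group identifier.
#' @return `sv_pseudohap` list: `group_id`, `member_ids`, `sequences`
#'   (named character, group-tagged contig names), `map` (data.frame chrom,
#'   ref_start, ref_len, alt_len), `contigs` (original contig names).
#' @export
implant_pseudohaplotype <- function(genome, group, group_id = 1L) {
  seqs <- genome
  map <- group[order(group$chrom, group$start),
               c("chrom", "start", "id"), drop = FALSE]
  map$ref_len <- nchar(group$ref[order(group$chrom, group$start)])
  map$alt_len <- nchar(group$alt[order(group$chrom, group$start)])
  names(map)[names(map) == "start"] <- "ref_start"
  for (chrom in unique(group$chrom)) {
    g <- group[group$chrom == chrom, , drop = FALSE]
    g <- g[order(-g$start), , drop = FALSE]
    s <- seqs[[chrom]]
    for (i in seq_len(nrow(g))) {
      obs <- substr(s, g$start[i] + 1L, g$start[i] + nchar(g$ref[i]))
      if (!identical(obs, g$ref[i])) {
        stop(sprintf("REF mismatch implanting %s at %s:%d", g$id[i], chrom,
                     g$start[i] + 1L))
      }
      s <- paste0(substr(s, 1L, g$start[i]), g$alt[i],
                  substr(s, g$start[i] + nchar(g$ref[i]) + 1L, nchar(s)))
    }
    seqs[[chrom]] <- s
  }
  names(seqs) <- paste0(names(seqs), "_group", group_id)
  structure(list(group_id = group_id, member_ids = group$id,
                 sequences = seqs, map = map, contigs = names(genome)),
            class = "sv_pseudohap")
}

#' Map a reference position onto a pseudo-haplotype
#'
#' @param ph `sv_pseudohap`.
#' @param chrom Original contig name.
#' @param pos 0-based reference position (must not fall strictly inside a
#'   replaced REF span).
#' @return 0-based position on the pseudo-haplotype contig.
#' @export
pseudohap_pos <- function(ph, chrom, pos) {
  m <- ph$map[ph$map$chrom == chrom, , drop = FALSE]
  before <- m$ref_start + m$ref_len <= pos
  pos + sum(m$alt_len[before] - m$ref_len[before])
}

#' Build all pseudo-haplotypes for a callset
#'
#' @param genome Genome (centromeres should be masked beforehand).
#' @param records `sv_records` table (masked records removed).
#' @return List of `sv_pseudohap`, one per non-overlapping group.
#' @export
build_pseudohaplotypes <- function(genome, records) {
  parts <- partition_nonoverlapping(records)
  lapply(sort(unique(parts$group_id)), function(g) {
    implant_pseudohaplotype(genome, parts[parts$group_id == g, , drop = FALSE],
                            group_id = g)
  })
}

#' Merge SV records assembled from one contig into a single record
#'
#' Connects multiple records from the same assembled contig into one record
#' by adding the intervening reference sequence to both alleles.
#'
#' @param records `sv_records` rows sharing one reference contig, sorted or
#'   not.
#' @param genome Genome.
#' @return One-row `sv_records` table (COMPLEX when more than one member).
#' @export
merge_contig_records <- function(records, genome) {
  if (nrow(records) == 1) return(records)
  if (length(unique(records$chrom)) != 1) {
    stop("cannot merge records on different chromosomes")
  }
  records <- records[order(records$start), , drop = FALSE]
  chrom <- records$chrom[1]
  ref <- records$ref[1]; alt <- records$alt[1]
  for (i in seq_len(nrow(records))[-1]) {
    spacer <- genome_seq(genome, chrom, records$end[i - 1L], records$start[i])
    ref <- paste0(ref, spacer, records$ref[i])
    alt <- paste0(alt, spacer, records$alt[i])
  }
  sv_records(id = paste(records$id, collapse = "+"), chrom = chrom,
             start = records$start[1], ref = ref, alt = alt)
}

#' Identify novel bubbles in an augmented graph
#'
#' A bubble of the augmented graph is novel when its distance to the closest
#' bubble of the original graph is at least `min_dist` bp (gap distance; an
#' empty original set makes every bubble novel).
#'
#' @param bubbles_aug,bubbles_orig data.frames (chrom, start, end).
#' @param min_dist Minimum distance (bp).
#' @return `bubbles_aug` with a logical `novel` column and `distance`.
#' @export
novel_bubble_filter <- function(bubbles_aug, bubbles_orig, min_dist = 1000) {
  if (nrow(bubbles_aug) == 0) {
    bubbles_aug$novel <- logical(0); bubbles_aug$distance <- numeric(0)
    return(bubbles_aug)
  }
  if (nrow(bubbles_orig) == 0) {
    bubbles_aug$novel <- TRUE
    bubbles_aug$distance <- Inf
    return(bubbles_aug)
  }
  ga <- GenomicRanges::GRanges(bubbles_aug$chrom,
                               IRanges::IRanges(bubbles_aug$start + 1L,
                                                pmax(bubbles_aug$end,
                                                     bubbles_aug$start + 1L)))
  go <- GenomicRanges::GRanges(bubbles_orig$chrom,
                               IRanges::IRanges(bubbles_orig$start + 1L,
                                                pmax(bubbles_orig$end,
                                                     bubbles_orig$start + 1L)))
  dtn <- GenomicRanges::distanceToNearest(ga, go)
  dist <- rep(Inf, nrow(bubbles_aug))
  dist[S4Vectors::queryHits(dtn)] <- S4Vectors::mcols(dtn)$distance
  bubbles_aug$distance <- dist
  bubbles_aug$novel <- dist >= min_dist
  bubbles_aug
}
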