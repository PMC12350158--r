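# End-to-end annotation drivers: per-insert retrotransposition pipeline
# (TSD -> orientation/tails -> transduction -> decomposition -> class), and
# a callset-level driver that falls through to VNTR and duplication rules
# for inserts not explained by the mobile-element engine.

#' Annotate one insert allele
#'
#' Runs the full retrotransposition annotation pipeline on a single insert
#' sequence at a known integration site.
#'
#' @param insert_seq Inserted bases (anchor removed).
#' @param ref_up,ref_down Reference flanks at the integration position.
#' @param genome Genome (named character vector) or NULL.
#' @param db `sv_consensus_db`.
#' @param exons Optional exon table (chrom, start, end, id).
#' @param tsd_max_len Maximum TSD length searched.
#' @param min_cov Coverage threshold for classification rules.
#' @param ... Further arguments to [detect_transductions()] and
#'   [decompose_insert()] are fixed at their defaults.
#' @return `sv_insert_annotation` with an added `orientation` field.
#' @export
annotate_insert <- function(insert_seq, ref_up, ref_down, genome, db,
                            exons = NULL, tsd_max_len = 50, min_cov = 0.75) {
  tsd <- find_tsd(insert_seq, ref_up, ref_down, max_len = tsd_max_len)
  ot <- orient_and_trim(insert_seq, tsd)
  td <- detect_transductions(ot$body, genome)
  chain <- decompose_insert(td$core, db, genome)
  ann <- classify_insert(chain, db, tail = ot$tail, tsd = tsd,
                         transduction = td$transduction, exons = exons,
                         min_cov = min_cov, core = td$core)
  ann$orientation <- ot$orientation
  ann
}

annotation_row <- function(id, ann) {
  td <- ann$transduction
  data.frame(
    id = id,
    class = ann$class,
    canonical = ann$canonical,
    family = ann$family,
    subfamily = ann$subfamily,
    orientation = if (is.null(ann$orientation)) NA_character_ else ann$orientation,
    tsd_len = if (is.null(ann$tsd)) 0L else ann$tsd$length,
    tail_len = if (is.null(ann$tail)) 0L else ann$tail$length,
    td_side = if (is.null(td)) NA_character_ else td$side,
    td_source_chrom = if (is.null(td) || is.null(td$source)) NA_character_ else td$source$chrom,
    td_source_start = if (is.null(td) || is.null(td$source)) NA_integer_ else td$source$start,
    td_source_end = if (is.null(td) || is.null(td$source)) NA_integer_ else td$source$end,
    coverage = ann$chain$coverage,
    full_length = ann$full_length,
    twin_priming = ann$twin_priming,
    flags = paste(ann$flags, collapse = ","),
    exon_count = ann$exon_count,
    stringsAsFactors = FALSE
  )
}

#' Annotate every resolved insertion in a callset
#'
#' @param records `sv_records` table.
#' @param genome Genome (named character vector).
#' @param db `sv_consensus_db`.
#' @param exons Optional exon table.
#' @param flank Flank length fetched around each integration site.
#' @param include_deletions Also annotate deleted sequences (classifies the
#'   removed allele with the same engine; reference MEIs).
#' @return data.frame with one row per annotated record (id, class,
#'   canonical, family, subfamily, TSD/tail lengths, transduction fields,
#'   coverage, flags) plus a list-column `annotation` holding the full
#'   objects.
#' @export
annotate_inserts <- function(records, genome, db, exons = NULL, flank = 100,
                             include_deletions = FALSE) {
  if (!is.null(genome) && is.null(attr(genome, "sv_seed_index"))) {
    genome <- index_targets(genome, 15)
  }
  rows <- list(); anns <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (isTRUE(r$unresolvable)) next
    if (!(identical(r$svtype, "INS") ||
          (include_deletions && identical(r$svtype, "DEL")))) next
    seq <- sv_allele_seq(r)
    # integration position: after the anchor base
    pos <- r$start + 1L
    up <- genome_seq(genome, r$chrom, pos - flank, pos)
    down_from <- if (identical(r$svtype, "DEL")) r$end else pos
    down <- genome_seq(genome, r$chrom, down_from, down_from + flank)
    ann <- annotate_insert(seq, up, down, genome, db, exons = exons)
    rows[[length(rows) + 1L]] <- annotation_row(r$id, ann)
    anns[[length(anns) + 1L]] <- ann
  }
  if (length(rows) == 0) {
    return(data.frame(id = character(0), class = character(0)))
  }
  out <- do.call(rbind, rows)
  out$annotation <- anns
  rownames(out) <- NULL
  out
}

#' Annotate a callset across the full class hierarchy
#'
#' Insertions are first run through the mobile-element engine; inserts left
#' unclassified fall through to the tandem-repeat (VNTR) rules and then the
#' duplication rules. Deleted sequences are tested against the VNTR rules
#' (VNTR contractions).
#'
#' @param records `sv_records` table.
#' @param genome Genome.
#' @param db `sv_consensus_db`.
#' @param exons Optional exon table.
#' @return data.frame with `id`, `class` and the mobile-element annotation
#'   columns where applicable.
#' @export
annotate_sv_callset <- function(records, genome, db, exons = NULL) {
  mei <- annotate_inserts(records, genome, db, exons = exons)
  out <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (isTRUE(r$unresolvable) || is.na(r$svtype) || r$svtype == "COMPLEX") next
    seq <- sv_allele_seq(r)
    row <- data.frame(id = r$id, class = "unclassified",
                      stringsAsFactors = FALSE)
    if (identical(r$svtype, "INS")) {
      m <- mei[mei$id == r$id, , drop = FALSE]
      if (nrow(m) && m$class[1] != "unclassified") {
        row$class <- m$class[1]
      } else {
        v <- classify_vntr(seq)
        if (!is.null(v)) {
          row$class <- v$class
        } else {
          d <- classify_duplication(seq, r$chrom, r$start + 1L, genome)
          if (!is.null(d)) row$class <- paste0("DUP_", d$class)
        }
      }
    } else if (identical(r$svtype, "DEL")) {
      v <- classify_vntr(seq)
      if (!is.null(v)) row$class <- v$class
    }
    out[[length(out) + 1L]] <- row
  }
  res <- do.call(rbind, out)
  merge(res, mei[setdiff(names(mei), c("class", "annotation"))],
        by = "id", all.x = TRUE, sort = FALSE)
}
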