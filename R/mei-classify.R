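# Insert decomposition and final class assignment. All classification rules
# are >=75% query-coverage rules evaluated on the optimal alignment chain,
# applied in a fixed precedence (most specific structure first):
# processed pseudogene -> 5' partnered transduction -> 3' partnered
# transduction -> orphan transduction -> solo element -> ERV -> NUMT ->
# non-canonical MEI -> unclassified.

# fraction of core covered by the query intervals of a hit subset
cov_frac <- function(hits, idx, core_len) {
  if (length(idx) == 0 || core_len == 0) return(0)
  interval_union_len(hits$query_start[idx], hits$query_end[idx]) / core_len
}

# overlap (bp) of one interval with a set of intervals on the same contig
overlap_bp <- function(start, end, track_start, track_end) {
  if (length(track_start) == 0) return(0L)
  sum(pmax(0L, pmin(end, track_end) - pmax(start, track_start)))
}

#' Decompose an insert core into consensus and genomic components
#'
#' Aligns the core against the consensus element database and, when the
#' consensus chain leaves at least `genome_trigger` of the core uncovered
#' (or an uncovered 5' prefix that could be a transduced segment), also
#' against the reference genome; the combined hits are chained with
#' [chain_best()]. Mitochondrial consensus entries are aligned circularly.
#'
#' @param core Trimmed, forward-oriented insert core.
#' @param db `sv_consensus_db`.
#' @param genome Optional genome for pseudogene/orphan/5'-transduction and
#'   NUMT evidence.
#' @param min_identity,seed_word,min_uniqueness Consensus alignment
#'   parameters.
#' @param genome_seed Seed length for genome-scale alignment.
#' @param genome_trigger Genome alignment runs when consensus coverage is
#'   below this fraction or a >=`min_prefix` bp 5' prefix is uncovered.
#' @param min_prefix Minimum uncovered 5' prefix (bp) triggering genome
#'   alignment.
#' @return `sv_chain` whose hits carry `kind` ("consensus"/"genome") and
#'   `family` columns.
#' @export
decompose_insert <- function(core, db, genome = NULL, min_identity = 0.8,
                             seed_word = 8, min_uniqueness = 10,
                             genome_seed = 15, genome_trigger = 0.75,
                             min_prefix = 30, min_hit_len = 25) {
  n <- nchar(core)
  if (n == 0) return(empty_chain(0L))
  targets <- db$seqs
  mt <- db$meta$name[db$meta$family == "MT"]
  doubled <- character(0)
  for (m in mt) {
    if (nchar(targets[[m]]) >= n) next
    targets[[m]] <- paste0(targets[[m]], targets[[m]])  # circular
    doubled <- c(doubled, m)
  }
  if (length(doubled)) {
    # drop stale precomputed indexes of the doubled entries
    idx <- attr(targets, "sv_seed_index")
    for (key in names(idx)) idx[[key]][doubled] <- NULL
    attr(targets, "sv_seed_index") <- idx
  }
  hits <- suppressWarnings(
    local_hits(core, targets, min_identity = min_identity,
               seed_word = seed_word, min_uniqueness = min_uniqueness,
               min_hit_len = min_hit_len)
  )
  if (nrow(hits)) {
    hits$kind <- "consensus"
    hits$family <- db_family(db, hits$target)
  }
  chain0 <- chain_best(hits, n)
  uncovered_prefix <- if (nrow(chain0$hits)) min(chain0$hits$query_start) else n
  if (!is.null(genome) &&
      (chain0$coverage < genome_trigger || uncovered_prefix >= min_prefix)) {
    gh <- suppressWarnings(
      local_hits(core, genome, min_identity = min_identity,
                 seed_word = genome_seed, min_uniqueness = min_uniqueness,
                 min_hit_len = min_hit_len)
    )
    if (nrow(gh)) {
      gh$kind <- "genome"
      gh$family <- NA_character_
      hits <- if (nrow(hits)) rbind(hits, gh) else gh
    }
  }
  chain <- chain_best(hits, n)
  if (!nrow(chain$hits)) {
    chain$hits$kind <- character(0)
    chain$hits$family <- character(0)
  }
  chain
}

# structural flags for the element hits of one family within a chain:
# 3' truncation, colinearity / twin-priming pattern.
element_structure <- function(hits, db, family, tol = 30) {
  fh <- hits[!is.na(hits$family) & hits$family == family, , drop = FALSE]
  flags <- character(0)
  twin <- FALSE
  if (nrow(fh) == 0) {
    return(list(flags = flags, twin = twin, full_length = FALSE))
  }
  fh <- fh[order(fh$query_start), , drop = FALSE]
  last <- db_last_part(db, family)
  on_last <- fh[fh$target == last$name, , drop = FALSE]
  if (nrow(on_last) == 0 || max(on_last$target_end) < last$length - tol) {
    flags <- c(flags, "truncated_3p")
  }
  strands <- fh$strand
  part <- db$meta$part_order[match(fh$target, db$meta$name)]
  ord <- part * 1e9 + fh$target_start
  colinear_plus <- all(strands == "+") && !is.unsorted(ord, strictly = FALSE)
  colinear_minus <- all(strands == "-") &&
    !is.unsorted(rev(ord), strictly = FALSE)
  twin <- nrow(fh) >= 2 && strands[1] == "-" && all(strands[-1] == "+")
  if (!colinear_plus && !colinear_minus && !twin) {
    flags <- c(flags, "internal_rearrangement")
  }
  cov_target <- sum(fh$target_end - fh$target_start)
  full_length <- cov_target >= 0.95 * db_family_len(db, family)
  list(flags = flags, twin = twin, full_length = full_length)
}

# dominant source interval of a set of genome hits
genome_source <- function(gh) {
  if (nrow(gh) == 0) return(NULL)
  dom <- names(sort(table(gh$target), decreasing = TRUE))[1]
  gd <- gh[gh$target == dom, , drop = FALSE]
  list(chrom = dom, start = min(gd$target_start), end = max(gd$target_end),
       strand = names(sort(table(gd$strand), decreasing = TRUE))[1])
}

#' Classify an insert from its decomposition chain
#'
#' Applies the >=75% coverage rules in fixed precedence. Canonical status
#' requires a terminal tail and a target-primed-reverse-transcription
#' compatible structure (colinear element components, intact 3' end; a
#' minus-strand 5' component followed by plus-strand components is the
#' twin-priming signature and remains canonical). Non-canonical MEIs carry
#' flags: `truncated_3p`, `no_polyA`, `internal_rearrangement`.
#'
#' @param chain `sv_chain` from [decompose_insert()].
#' @param db `sv_consensus_db`.
#' @param tail `sv_polytail` or NULL.
#' @param tsd `sv_tsd` or NULL.
#' @param transduction 3' transduction from [detect_transductions()], or
#'   NULL.
#' @param exons Optional data.frame (chrom, start, end, id) of exon
#'   intervals for pseudogene calls.
#' @param min_cov Coverage threshold for every class rule.
#' @param min_prefix Minimum 5' genomic segment (bp) for a 5' transduction.
#' @param core Core sequence (used for L1 subfamily diagnostics).
#' @return `sv_insert_annotation` list: `class`, `canonical`, `tail`, `tsd`,
#'   `transduction`, `chain`, `subfamily`, `family`, `full_length`, `flags`,
#'   `twin_priming`, `exon_count`, `satisfied_rules`.
#' @export
classify_insert <- function(chain, db, tail = NULL, tsd = NULL,
                            transduction = NULL, exons = NULL,
                            min_cov = 0.75, min_prefix = 30, core = NULL) {
  hits <- chain$hits
  n <- chain$query_len
  ann <- list(class = "unclassified", canonical = FALSE, tail = tail,
              tsd = tsd, transduction = transduction, chain = chain,
              subfamily = NA_character_, family = NA_character_,
              full_length = FALSE, flags = character(0),
              twin_priming = FALSE, exon_count = NA_integer_,
              satisfied_rules = character(0))
  class(ann) <- "sv_insert_annotation"
  if (is.null(hits) || nrow(hits) == 0 || n == 0) return(ann)

  is_genome <- hits$kind == "genome"
  mei_idx <- which(!is_genome & hits$family %in% MEI_FAMILIES)
  erv_idx <- which(!is_genome & hits$family %in% c("LTR", "ERVK"))
  mt_idx <- which(!is_genome & hits$family == "MT")
  gen_idx <- which(is_genome)

  # exonic split of genome hits
  exonic <- rep(FALSE, nrow(hits))
  if (!is.null(exons) && length(gen_idx)) {
    for (i in gen_idx) {
      ex <- exons[exons$chrom == hits$target[i], , drop = FALSE]
      ov <- overlap_bp(hits$target_start[i], hits$target_end[i],
                       ex$start, ex$end)
      exonic[i] <- ov >= 0.5 * hits$length[i]
    }
  }
  cov_mei <- cov_frac(hits, mei_idx, n)
  cov_erv <- cov_frac(hits, erv_idx, n)
  cov_mt <- cov_frac(hits, mt_idx, n)
  cov_exonic <- cov_frac(hits, gen_idx[exonic[gen_idx]], n)
  cov_gen_nonex <- cov_frac(hits, gen_idx[!exonic[gen_idx]], n)
  fam_cov <- vapply(MEI_FAMILIES, function(f) {
    cov_frac(hits, which(!is_genome & hits$family == f), n)
  }, numeric(1))
  dom_family <- MEI_FAMILIES[which.max(fam_cov)]
  has_tail <- !is.null(tail)

  satisfied <- character(0)
  if (cov_exonic >= min_cov) satisfied <- c(satisfied, "pseudogene")
  # 5' transduction: genomic prefix ahead of the element components
  prefix_ok <- FALSE
  if (length(mei_idx)) {
    e0 <- min(hits$query_start[mei_idx])
    pre_idx <- gen_idx[hits$query_end[gen_idx] <= e0 + 10]
    if (e0 >= min_prefix && length(pre_idx)) {
      pre_cov <- interval_union_len(
        pmin(hits$query_start[pre_idx], e0),
        pmin(hits$query_end[pre_idx], e0)
      ) / e0
      prefix_ok <- pre_cov >= 0.8 && (cov_mei + cov_frac(hits, pre_idx, n)) >= min_cov
    }
  }
  if (prefix_ok) satisfied <- c(satisfied, "td_5p")
  if (!is.null(transduction) && cov_mei >= min_cov) {
    satisfied <- c(satisfied, "td_3p")
  }
  if (cov_gen_nonex >= min_cov && cov_mei < 0.25) {
    satisfied <- c(satisfied, "orphan")
  }
  if (max(fam_cov) >= min_cov) satisfied <- c(satisfied, "solo")
  if (cov_erv >= min_cov) satisfied <- c(satisfied, "erv")
  if (cov_mt >= min_cov) satisfied <- c(satisfied, "numt")
  ann$satisfied_rules <- satisfied

  struct <- element_structure(hits, db, dom_family)
  structural_flags <- struct$flags
  ann$twin_priming <- struct$twin
  ann$full_length <- struct$full_length

  pick_subfamily <- function(family) {
    fh <- hits[!is.na(hits$family) & hits$family == family, , drop = FALSE]
    if (!nrow(fh)) return(NA_character_)
    if (family == "L1" && !is.null(core)) {
      return(l1_subfamily(chain, core, db))
    }
    best <- fh$target[which.max(fh$score)]
    db$meta$subfamily[match(best, db$meta$name)]
  }

  if (has_tail && "pseudogene" %in% satisfied) {
    ann$class <- "processed_pseudogene"
    ann$canonical <- TRUE
    ex_hit <- gen_idx[exonic[gen_idx]]
    if (!is.null(exons)) {
      ids <- character(0)
      for (i in ex_hit) {
        ex <- exons[exons$chrom == hits$target[i], , drop = FALSE]
        keep <- pmin(hits$target_end[i], ex$end) -
          pmax(hits$target_start[i], ex$start) > 0
        ids <- c(ids, ex$id[keep])
      }
      ann$exon_count <- length(unique(ids))
    }
    return(ann)
  }
  if (has_tail && "td_5p" %in% satisfied &&
      !length(structural_flags)) {
    e0 <- min(hits$query_start[mei_idx])
    pre_idx <- gen_idx[hits$query_end[gen_idx] <= e0 + 10]
    ann$class <- "partnered_td_5p"
    ann$canonical <- TRUE
    ann$family <- dom_family
    ann$subfamily <- pick_subfamily(dom_family)
    ann$transduction <- list(
      side = "5p", sequence = if (!is.null(core)) substr(core, 1L, e0) else NULL,
      aligned_fraction = cov_frac(hits, pre_idx, e0) * n / max(1, e0),
      source = genome_source(hits[pre_idx, , drop = FALSE])
    )
    return(ann)
  }
  if (has_tail && "td_3p" %in% satisfied && !length(structural_flags)) {
    ann$class <- "partnered_td_3p"
    ann$canonical <- TRUE
    ann$family <- dom_family
    ann$subfamily <- pick_subfamily(dom_family)
    return(ann)
  }
  if (has_tail && "orphan" %in% satisfied) {
    ann$class <- "orphan_td"
    ann$canonical <- TRUE
    ann$transduction <- list(
      side = "orphan", sequence = NULL,
      aligned_fraction = cov_gen_nonex,
      source = genome_source(hits[gen_idx[!exonic[gen_idx]], , drop = FALSE])
    )
    return(ann)
  }
  if (has_tail && "solo" %in% satisfied && !length(structural_flags)) {
    ann$class <- paste0("solo_", dom_family)
    ann$canonical <- TRUE
    ann$family <- dom_family
    ann$subfamily <- pick_subfamily(dom_family)
    return(ann)
  }
  if ("erv" %in% satisfied) {
    erv <- hits[erv_idx, , drop = FALSE]
    has_internal <- any(erv$family == "ERVK")
    ann$class <- if (has_internal) "ERVK" else "solo_LTR"
    ann$family <- if (has_internal) "ERVK" else "LTR"
    ann$canonical <- FALSE
    return(ann)
  }
  if ("numt" %in% satisfied) {
    ann$class <- "NUMT"
    ann$family <- "MT"
    return(ann)
  }
  if (cov_mei >= min_cov) {
    ann$class <- "non_canonical_MEI"
    ann$family <- dom_family
    flags <- structural_flags
    if (!has_tail) flags <- c(flags, "no_polyA")
    ann$flags <- flags
    return(ann)
  }
  ann
}

#' L1 subfamily from diagnostic consensus positions
#'
#' Reads the bases mapped to L1 consensus positions 5929-5931 (1-based):
#' `ACG` marks pre-Ta, `ACA` marks Ta, refined via positions 5535 and 5538
#' (G and C: Ta-0; T and G: Ta-1). Any other profile, or diagnostic
#' positions not covered by a plus-strand alignment, leaves the subfamily
#' undetermined.
#'
#' @param chain `sv_chain` mapping the core onto consensus coordinates.
#' @param core Core sequence.
#' @param db `sv_consensus_db` (the L1 entry defines the coordinate frame).
#' @param triplet_pos,ta_pos 1-based diagnostic consensus positions.
#' @return "pre-Ta", "Ta", "Ta-0", "Ta-1" or "undetermined".
#' @export
l1_subfamily <- function(chain, core, db, triplet_pos = 5929:5931,
                         ta_pos = c(5535, 5538)) {
  l1 <- db$meta$name[db$meta$family == "L1"][1]
  if (is.na(l1)) return("undetermined")
  fh <- chain$hits[chain$hits$target == l1 & chain$hits$strand == "+", ,
                   drop = FALSE]
  read_pos <- function(p) {
    for (i in seq_len(nrow(fh))) {
      if (fh$target_start[i] < p && p <= fh$target_end[i]) {
        q <- fh$query_start[i] + (p - 1L - fh$target_start[i]) + 1L
        return(substr(core, q, q))
      }
    }
    NA_character_
  }
  trip <- vapply(triplet_pos, read_pos, character(1))
  if (any(is.na(trip))) return("undetermined")
  trip <- paste(trip, collapse = "")
  if (trip == "ACG") return("pre-Ta")
  if (trip != "ACA") return("undetermined")
  ta <- vapply(ta_pos, read_pos, character(1))
  if (any(is.na(ta))) return("Ta")
  if (ta[1] == "G" && ta[2] == "C") return("Ta-0")
  if (ta[1] == "T" && ta[2] == "G") return("Ta-1")
  "Ta"
}

#' Classify an endogenous retrovirus insert
#'
#' Assigned only when at least `min_cov` of the core is covered by hits to
#' the retroviral database (LTR and internal proviral consensus): LTR
#' sequence alone gives `solo_LTR`; LTR plus internal sequence (or internal
#' alone) gives `ERVK`.
#'
#' @param core Insert core sequence.
#' @param db `sv_consensus_db` containing `LTR` and `ERVK` family entries.
#' @param min_cov Coverage threshold.
#' @param ... Passed to [local_hits()].
#' @return NULL or list with `class`, `n_ltr` (distinct LTR segments,
#'   0-2), `has_internal`, `coverage`.
#' @export
classify_erv <- function(core, db, min_cov = 0.75, ...) {
  nm <- db$meta$name[db$meta$family %in% c("LTR", "ERVK")]
  if (length(nm) == 0 || nchar(core) == 0) return(NULL)
  hits <- suppressWarnings(local_hits(core, db$seqs[nm], seed_word = 8,
                                      min_hit_len = 25, ...))
  chain <- chain_best(hits, nchar(core))
  if (chain$coverage < min_cov) return(NULL)
  fam <- db_family(db, chain$hits$target)
  n_ltr <- sum(fam == "LTR")
  has_internal <- any(fam == "ERVK")
  list(class = if (has_internal) "ERVK" else "solo_LTR",
       n_ltr = n_ltr, has_internal = has_internal,
       coverage = chain$coverage)
}

#' Classify a nuclear mitochondrial insertion (NUMT)
#'
#' The mitochondrial reference is treated as circular: alignment runs
#' against the doubled sequence and fragment coordinates are wrapped back
#' onto the circle, so inserts spanning the origin are reported as two
#' wrapped fragments.
#'
#' @param core Insert core sequence.
#' @param mito_ref Mitochondrial reference sequence (character scalar).
#' @param min_cov Minimum fraction of the core covered by mitochondrial
#'   hits.
#' @param seed_word Seed length.
#' @return NULL, or list with `coverage` and `fragments` (data.frame of
#'   0-based half-open mitochondrial intervals).
#' @export
classify_numt <- function(core, mito_ref, min_cov = 0.75, seed_word = 11) {
  L <- nchar(mito_ref)
  target <- c(MT = if (nchar(core) > L) paste0(mito_ref, mito_ref) else
    paste0(mito_ref, substr(mito_ref, 1L, min(L, nchar(core)))))
  hits <- suppressWarnings(
    local_hits(core, target, seed_word = seed_word, min_uniqueness = 0)
  )
  chain <- chain_best(hits, nchar(core))
  if (chain$coverage < min_cov) return(NULL)
  frags <- list()
  for (i in seq_len(nrow(chain$hits))) {
    s <- chain$hits$target_start[i] %% L
    e <- s + chain$hits$length[i]
    if (e <= L) {
      frags[[length(frags) + 1L]] <- data.frame(start = s, end = e)
    } else {
      frags[[length(frags) + 1L]] <- data.frame(start = s, end = L)
      frags[[length(frags) + 1L]] <- data.frame(start = 0L, end = e - L)
    }
  }
  list(coverage = chain$coverage, fragments = do.call(rbind, frags))
}
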