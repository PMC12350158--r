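# Breakpoint-junction homology quantification and formation-mechanism
# classification. Two complementary measurements are made per SV:
# (1) microhomology: the maximal exact junction-spanning match, computed
#     directly on the sequence and capped at 50 bp;
# (2) windowed homology scan: co-directional local alignments between window
#     pairs around the two breakpoints that span both breakpoints at the
#     same relative position, capturing long (>=16 bp) homologous flanks.

#' Implant an insertion allele into its contig
#'
#' Produces a modified contig on which both junction coordinates exist, plus
#' a coordinate map for translating downstream intervals back to reference
#' space. Deletions need no modification (both breakpoints are already on
#' the reference).
#'
#' @param genome Genome.
#' @param record One-row `sv_records` slice.
#' @return List with `seq` (modified contig), `bl`/`br` (0-based junction
#'   positions on `seq`), `shift_at` (0-based reference position after which
#'   coordinates shift) and `shift` (bp).
#' @export
implant_allele <- function(genome, record) {
  if (isTRUE(record$unresolvable)) stop("record is unresolvable: ", record$id)
  contig <- genome[[record$chrom]]
  if (is.null(contig)) stop("contig not found: ", record$chrom)
  if (identical(record$svtype, "DEL")) {
    bl <- record$start + 1L            # after the anchor base
    return(list(seq = contig, bl = bl, br = record$end,
                shift_at = record$end, shift = 0L))
  }
  n <- nchar(contig)
  ref_span <- substr(contig, record$start + 1L, record$end)
  if (!identical(ref_span, record$ref)) {
    stop(sprintf("REF mismatch at %s:%d", record$chrom, record$start + 1L))
  }
  new_seq <- paste0(substr(contig, 1L, record$start), record$alt,
                    substr(contig, record$end + 1L, n))
  bl <- record$start + 1L
  br <- bl + (nchar(record$alt) - 1L)
  list(seq = new_seq, bl = bl, br = br, shift_at = record$end,
       shift = nchar(record$alt) - nchar(record$ref))
}

# translate a 0-based position on the implanted contig back to reference;
# positions inside an inserted allele project to the insertion point
implant_to_ref <- function(pos, imp) {
  if (imp$shift == 0L) return(pos)
  ifelse(pos <= imp$bl, pos,
         ifelse(pos >= imp$br, pos - imp$shift, imp$bl))
}

#' Microhomology length at an SV junction
#'
#' The maximal exact junction-spanning match: the sum of the exact left and
#' right extensions at the junction, capped at `cap` bp. For insertions at
#' most the first and last `insert_probe` bp of the inserted sequence are
#' probed; flanks are probed over 2 kb.
#'
#' @param record One-row `sv_records` slice.
#' @param genome Genome.
#' @param cap Reported maximum (larger values are set to `cap`).
#' @param insert_probe Probe length into the insert.
#' @param flank_probe Probe length into the flanks.
#' @return Integer microhomology length.
#' @export
microhomology_len <- function(record, genome, cap = 50, insert_probe = 50,
                              flank_probe = 2000) {
  # the exact extension cannot exceed the cap, so probing cap bases of
  # flank suffices regardless of the nominal probe length
  flank_probe <- min(flank_probe, cap + 1L)
  chrom <- record$chrom
  if (identical(record$svtype, "DEL")) {
    bl <- record$start + 1L
    br <- record$end
    right <- lcp_len(genome_seq(genome, chrom, bl, bl + flank_probe),
                     genome_seq(genome, chrom, br, br + flank_probe),
                     cap = cap)
    left <- lcs_len(genome_seq(genome, chrom, max(0, bl - flank_probe), bl),
                    genome_seq(genome, chrom, max(0, br - flank_probe), br),
                    cap = cap)
    return(as.integer(min(cap, right + left)))
  }
  if (identical(record$svtype, "INS")) {
    ins <- sv_allele_seq(record)
    pos <- record$start + 1L
    probe_head <- substr(ins, 1L, min(nchar(ins), insert_probe))
    probe_tail <- substr(ins, max(1L, nchar(ins) - insert_probe + 1L),
                         nchar(ins))
    right <- lcp_len(probe_head,
                     genome_seq(genome, chrom, pos, pos + flank_probe),
                     cap = cap)
    left <- lcs_len(probe_tail,
                    genome_seq(genome, chrom, max(0, pos - flank_probe), pos),
                    cap = cap)
    return(as.integer(min(cap, right + left)))
  }
  NA_integer_
}

#' Reference microhomology implementation
#'
#' Character-by-character maximal exact junction extension; independent
#' reference used to validate [microhomology_len()].
#'
#' @inheritParams microhomology_len
#' @return Integer microhomology length.
#' @export
microhomology_len_naive <- function(record, genome, cap = 50,
                                    insert_probe = 50) {
  chrom <- record$chrom
  contig <- genome[[chrom]]
  n <- nchar(contig)
  at <- function(p) if (p >= 1 && p <= n) substr(contig, p, p) else ""
  if (identical(record$svtype, "DEL")) {
    bl <- record$start + 1L; br <- record$end
    right <- 0L
    while (right < cap && at(bl + right + 1L) != "" &&
           at(bl + right + 1L) == at(br + right + 1L)) right <- right + 1L
    left <- 0L
    while (left < cap && at(bl - left) != "" &&
           at(bl - left) == at(br - left)) left <- left + 1L
    return(as.integer(min(cap, right + left)))
  }
  ins <- sv_allele_seq(record)
  pos <- record$start + 1L
  li <- nchar(ins)
  right <- 0L
  while (right < cap && right < insert_probe && right < li &&
         substr(ins, right + 1L, right + 1L) == at(pos + right + 1L)) {
    right <- right + 1L
  }
  left <- 0L
  while (left < cap && left < insert_probe && left < li &&
         substr(ins, li - left, li - left) == at(pos - left)) {
    left <- left + 1L
  }
  as.integer(min(cap, right + left))
}

#' Windowed homology scan around SV breakpoints
#'
#' Searches co-directional local alignments between window pairs around the
#' two breakpoints: symmetric windows with the given paddings (pairs that
#' would overlap are skipped) and asymmetric windows of SV length shifted in
#' sixths along the breakpoints. A passing alignment must span both
#' breakpoints and contain them at the same relative position (within
#' `rel_tol` of the alignment length). The longest passing homology across
#' all configurations is reported. Insertions are implanted first; arm
#' intervals are returned on the implanted contig together with their
#' reference projections.
#'
#' @param record One-row `sv_records` slice.
#' @param genome Genome.
#' @param min_identity Minimum alignment identity.
#' @param word Seed word size.
#' @param min_len Minimum homology length reported (shorter junction matches
#'   are microhomology territory).
#' @param paddings Symmetric window paddings (bp).
#' @param rel_tol Tolerance on the relative breakpoint position.
#' @return NULL, or list with `length`, `identity`, `arm_left`/`arm_right`
#'   (0-based half-open intervals, reference-projected) and `padding`.
#' @export
homology_scan <- function(record, genome, min_identity = 0.8, word = 5,
                          min_len = 16,
                          paddings = c(50, 100, 200, 400, 1000, 2000, 5000,
                                       10000),
                          rel_tol = 0.05) {
  imp <- implant_allele(genome, record)
  S <- imp$seq; ns <- nchar(S)
  bl <- imp$bl; br <- imp$br
  L <- br - bl
  configs <- list()
  for (w in paddings) {
    if (2 * w > L) next  # windows would overlap
    configs[[length(configs) + 1L]] <- c(bl - w, bl + w, br - w, br + w)
  }
  if (L >= 6) {
    for (k in 0:6) {
      up <- round(k * L / 6); down <- L - up
      configs[[length(configs) + 1L]] <-
        c(bl - up, bl + down, br - up, br + down)
    }
  }
  best <- NULL
  for (cf in configs) {
    as <- max(0L, cf[1]); ae <- min(ns, cf[2])
    bs <- max(0L, cf[3]); be <- min(ns, cf[4])
    if (ae - as < min_len || be - bs < min_len) next
    if (ae > bs) next  # overlapping windows are skipped
    rel_bl <- bl - as
    rel_br <- br - bs
    if (rel_bl < 0 || rel_bl > ae - as || rel_br < 0 || rel_br > be - bs) next
    A <- substr(S, as + 1L, ae)
    B <- setNames(substr(S, bs + 1L, be), "right")
    hits <- suppressWarnings(
      local_hits(A, B, min_identity = min_identity, seed_word = word,
                 min_uniqueness = 0, both_strands = FALSE,
                 min_hit_len = min_len)
    )
    if (nrow(hits) == 0) next
    # slack tolerates mismatch-trimmed hit ends right at the junction
    slack <- pmax(5, round(rel_tol * hits$length))
    span_q <- hits$query_start - slack <= rel_bl &
      rel_bl <= hits$query_end + slack
    span_t <- hits$target_start - slack <= rel_br &
      rel_br <= hits$target_end + slack
    relpos_q <- (rel_bl - hits$query_start) / hits$length
    relpos_t <- (rel_br - hits$target_start) / hits$length
    ok <- span_q & span_t & abs(relpos_q - relpos_t) <= rel_tol
    if (!any(ok)) next
    h <- hits[ok, , drop = FALSE]
    h <- h[which.max(h$length), , drop = FALSE]
    if (is.null(best) || h$length > best$length) {
      arm_left <- c(as + h$query_start, as + h$query_end)
      arm_right <- c(bs + h$target_start, bs + h$target_end)
      best <- list(
        length = h$length, identity = h$identity,
        arm_left = list(chrom = record$chrom,
                        start = implant_to_ref(arm_left[1], imp),
                        end = implant_to_ref(arm_left[2], imp)),
        arm_right = list(chrom = record$chrom,
                         start = implant_to_ref(arm_right[1], imp),
                         end = implant_to_ref(arm_right[2], imp)),
        padding = cf
      )
      # an arm fully inside the current windows cannot grow in larger ones;
      # the margin allows for mismatch-trimmed hit ends at low identity
      margin <- 30L
      if (h$query_start > margin && h$query_end < (ae - as) - margin &&
          h$target_start > margin && h$target_end < (be - bs) - margin) {
        break
      }
    }
  }
  best
}

#' Formation-mechanism label from junction homology
#'
#' SVs whose flank homology is allele-structural (VNTRs, tandem duplications
#' and MEIs) are excluded from mechanism calls. Otherwise the homology
#' length is binned: 0 blunt; 1-15 end-joining processes (NHEJ / alt-EJ /
#' MMBIR); 16-49 homology-independent; >=50 homology-directed repair (HDR);
#' >=200 non-allelic homologous recombination (NAHR, the more specific label
#' within the HDR range).
#'
#' @param hom_len Junction homology length (bp).
#' @param excluded TRUE for VNTR / tandem duplication / MEI records.
#' @return Mechanism label.
#' @export
classify_mechanism <- function(hom_len, excluded = FALSE) {
  if (excluded) return("unassigned")
  if (is.na(hom_len)) return("unassigned")
  if (hom_len >= 200) return("NAHR")
  if (hom_len >= 50) return("HDR")
  if (hom_len >= 16) return("homology_independent")
  if (hom_len >= 1) return("NHEJ_altEJ_MMBIR")
  "blunt"
}

hom_class_bin <- function(hom_len) {
  if (is.na(hom_len)) return(NA_character_)
  if (hom_len >= 200) return("homology_ge200")
  if (hom_len >= 50) return("homology_ge50")
  if (hom_len >= 16) return("microhomology_16_49")
  if (hom_len >= 1) return("microhomology_1_15")
  "blunt"
}

#' Full junction call for one SV
#'
#' Combines the capped microhomology measurement and the windowed homology
#' scan (the larger of the two is the reported homology length), bins the
#' result, and assigns a formation mechanism.
#'
#' @param record One-row `sv_records` slice.
#' @param genome Genome.
#' @param excluded TRUE when the SV class (VNTR/tandem dup/MEI) excludes it
#'   from mechanism calling.
#' @param ... Passed to [homology_scan()].
#' @return `sv_junction_call` list: `sv_id`, `hom_len`, `microhomology`,
#'   `scan` (NULL or scan result), `hom_class`, `mechanism`,
#'   `mediating_repeat` (NA until annotated), `sd_mediated`.
#' @export
junction_call <- function(record, genome, excluded = FALSE, ...) {
  micro <- microhomology_len(record, genome)
  scan <- homology_scan(record, genome, ...)
  hom <- max(micro, if (is.null(scan)) 0L else scan$length, na.rm = TRUE)
  structure(list(
    sv_id = record$id, hom_len = hom, microhomology = micro, scan = scan,
    hom_class = hom_class_bin(hom),
    mechanism = classify_mechanism(hom, excluded = excluded),
    mediating_repeat = NA_character_, sd_mediated = FALSE
  ), class = "sv_junction_call")
}

# coverage of an arm by same-class annotations, plus element-span checks
arm_repeat_stats <- function(arm, track) {
  tr <- track[track$chrom == arm$chrom, , drop = FALSE]
  ov <- pmin(arm$end, tr$end) - pmax(arm$start, tr$start)
  keep <- ov > 0
  tr <- tr[keep, , drop = FALSE]; ov <- ov[keep]
  if (!nrow(tr)) return(NULL)
  alen <- arm$end - arm$start
  data.frame(class = tr$class, ov = ov,
             arm_frac = ov / alen,
             elem_frac = ov / (tr$end - tr$start),
             elem_len = tr$end - tr$start,
             name = if (!is.null(tr$name)) tr$name else NA_character_,
             stringsAsFactors = FALSE)
}

#' Annotate repeat- and SD-mediation of a junction call
#'
#' A call is repeat-mediated when at least 85% of the bases of both
#' homologous regions intersect annotations of the same repeat class and at
#' least one homologous region spans 85% of its annotated element. It is
#' SD-mediated when a segmental duplication covers more than 85% of a
#' homologous region and the overlap spans more than 200 bases or at least
#' half of the SD.
#'
#' @param call `sv_junction_call` with a scan result.
#' @param repeat_track data.frame (chrom, start, end, class, name).
#' @param sd_track data.frame (chrom, start, end, name).
#' @param arm_frac,elem_frac The two 85% thresholds.
#' @param sd_min_bp,sd_min_frac SD rule thresholds (200 bp / 50%).
#' @return The call with `mediating_repeat` and `sd_mediated` updated.
#' @export
annotate_repeat_or_sd_mediated <- function(call, repeat_track = NULL,
                                           sd_track = NULL, arm_frac = 0.85,
                                           elem_frac = 0.85, sd_min_bp = 200,
                                           sd_min_frac = 0.5) {
  if (is.null(call$scan)) return(call)
  if (!is.null(repeat_track) && nrow(repeat_track) == 0) repeat_track <- NULL
  if (!is.null(sd_track) && nrow(sd_track) == 0) sd_track <- NULL
  arms <- list(call$scan$arm_left, call$scan$arm_right)
  if (!is.null(repeat_track)) {
    s1 <- arm_repeat_stats(arms[[1]], repeat_track)
    s2 <- arm_repeat_stats(arms[[2]], repeat_track)
    if (!is.null(s1) && !is.null(s2)) {
      for (cl in intersect(unique(s1$class), unique(s2$class))) {
        cov1 <- sum(s1$arm_frac[s1$class == cl])
        cov2 <- sum(s2$arm_frac[s2$class == cl])
        spans <- c(s1$elem_frac[s1$class == cl], s2$elem_frac[s2$class == cl])
        if (cov1 >= arm_frac && cov2 >= arm_frac &&
            any(spans >= elem_frac)) {
          call$mediating_repeat <- cl
          break
        }
      }
    }
  }
  if (!is.null(sd_track)) {
    sdt <- sd_track
    sdt$class <- "SD"
    for (arm in arms) {
      st <- arm_repeat_stats(arm, sdt)
      if (is.null(st)) next
      hit <- st$arm_frac > arm_frac &
        (st$ov > sd_min_bp | st$ov >= sd_min_frac * st$elem_len)
      if (any(hit)) { call$sd_mediated <- TRUE; break }
    }
  }
  call
}

#' Junction calls for a whole callset
#'
#' @param records `sv_records` table.
#' @param genome Genome.
#' @param excluded_ids Record ids excluded from mechanism calling (VNTR /
#'   tandem duplication / MEI annotations).
#' @param repeat_track,sd_track Optional mediation tracks.
#' @param ... Passed to [junction_call()].
#' @return data.frame of junction calls (one row per resolved DEL/INS).
#' @export
annotate_junctions <- function(records, genome, excluded_ids = character(0),
                               repeat_track = NULL, sd_track = NULL, ...) {
  rows <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (isTRUE(r$unresolvable) || !r$svtype %in% c("DEL", "INS")) next
    call <- junction_call(r, genome, excluded = r$id %in% excluded_ids, ...)
    call <- annotate_repeat_or_sd_mediated(call, repeat_track, sd_track)
    rows[[length(rows) + 1L]] <- data.frame(
      id = r$id, svtype = r$svtype, svlen = r$svlen,
      hom_len = call$hom_len, microhomology = call$microhomology,
      scan_len = if (is.null(call$scan)) NA_integer_ else call$scan$length,
      hom_class = call$hom_class, mechanism = call$mechanism,
      mediating_repeat = call$mediating_repeat,
      sd_mediated = call$sd_mediated, stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(id = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
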