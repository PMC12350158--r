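# Seeded synthetic-data generator: random genomes, consensus-element
# stand-ins, implanted SVs with ground-truth labels, and haplotype panels
# for the recurrence screen. All randomness flows through the seed argument
# (withr::with_seed); regeneration from the same seed is bit-identical.
#
# Planted features are constructed to be maximal (guard bases prevent a
# planted tail, TSD or microhomology tract from extending by chance into
# its context), so the truth labels are well-defined quantities of the
# sequence itself rather than properties of any particular detector.

random_dna <- function(n, gc = 0.41) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Simulate a random genome
#'
#' @param length Contig length (bp).
#' @param gc GC fraction.
#' @param seed Integer seed (NULL leaves the RNG state alone).
#' @param name Contig name.
#' @return Named character vector of length 1.
#' @export
simulate_genome <- function(length, gc = 0.41, seed = NULL, name = "chrS") {
  with_seed(seed, setNames(random_dna(length, gc), name))
}

# break any poly(A)/poly(T)-qualifying tract by substituting spaced bases
strip_tracts <- function(seq, bases = c("A", "T"), min_len = 10,
                         min_purity = 0.90) {
  for (b in bases) {
    repeat {
      tr <- poly_tracts(seq, b, min_len = min_len, min_purity = min_purity,
                        max_tract = 200L)
      if (nrow(tr) == 0) break
      ch <- strsplit(seq, "")[[1]]
      sub <- if (b == "A") "G" else "C"
      for (i in seq_len(nrow(tr))) {
        at <- seq.int(tr$start[i] + 3L, tr$end[i], by = 6L)
        ch[at] <- sub
      }
      seq <- paste(ch, collapse = "")
    }
  }
  seq
}

# guard pattern free of A and T, used at element ends so planted tails stay
# maximal
GUARD_5 <- "GCGGCCGCGGCC"
GUARD_3 <- "CCGGCGCCGGCG"

make_element <- function(n, gc = 0.45) {
  s <- strip_tracts(random_dna(n, gc))
  paste0(GUARD_5, substr(s, 13L, n - 12L), GUARD_3)
}

#' Synthetic consensus element database
#'
#' Short stand-ins for the consensus databases of the real annotators: a
#' 300-bp pseudo-Alu, a 6-kb pseudo-L1 carrying diagnostic subfamily bases
#' at consensus positions 5929-5931 and 5535/5538, three SVA components
#' (Alu-like, VNTR, SINE-R), an LTR, an ERVK internal sequence and a 3-kb
#' circular mitochondrial stand-in. Elements are built without internal
#' poly(A/T) tracts and with A/T-free terminal guards so planted tails and
#' transduction splits are unambiguous.
#'
#' @param seed Integer seed.
#' @param l1_triplet Bases planted at L1 positions 5929-5931.
#' @param l1_ta Bases planted at positions 5535 and 5538.
#' @return `sv_consensus_db`.
#' @export
synthetic_consensus_db <- function(seed = 1, l1_triplet = "ACA",
                                   l1_ta = c("T", "G")) {
  with_seed(seed, {
    l1 <- make_element(6000)
    ch <- strsplit(l1, "")[[1]]
    ch[5929:5931] <- strsplit(l1_triplet, "")[[1]]
    ch[c(5535, 5538)] <- l1_ta
    l1 <- paste(ch, collapse = "")
    seqs <- c(
      Alu = make_element(300),
      L1 = l1,
      SVA_alu_like = make_element(350),
      SVA_vntr = make_element(500),
      SVA_sine_r = make_element(450),
      LTR5 = make_element(400),
      ERVK_int = make_element(2000),
      MT = strip_tracts(random_dna(3000, 0.44))
    )
    meta <- data.frame(
      name = names(seqs),
      family = c("Alu", "L1", "SVA", "SVA", "SVA", "LTR", "ERVK", "MT"),
      part_order = c(1L, 1L, 1L, 2L, 3L, 1L, 1L, 1L),
      subfamily = c("AluSyn", NA, "SVA_E", "SVA_E", "SVA_E", "LTR5syn",
                    "ERVKsyn", NA),
      stringsAsFactors = FALSE
    )
    consensus_db(seqs, meta)
  })
}

# full element body for a family (SVA concatenates its parts in order)
family_body <- function(db, family) {
  m <- db$meta[db$meta$family == family, , drop = FALSE]
  m <- m[order(m$part_order), , drop = FALSE]
  paste(db$seqs[m$name], collapse = "")
}

# pick n well-separated implant sites on a single-contig genome
pick_sites <- function(genome_len, n, spacing = 12000, margin = 30000) {
  lo <- margin; hi <- genome_len - margin
  slots <- floor((hi - lo) / spacing)
  if (slots < n) stop("genome too short for ", n, " implant sites")
  idx <- sort(sample.int(slots, n))
  lo + (idx - 1L) * spacing + sample.int(spacing / 2, n)
}

base_at <- function(seq, pos1) substr(seq, pos1, pos1)

set_base <- function(seq, pos1, b) {
  substr(seq, pos1, pos1) <- b
  seq
}

other_base <- function(b) setdiff(DNA_BASES, b)[1]

# Build one MEI insert allele at 0-based site p on contig `s`. Returns
# list(insert, truth fields...). May nudge the site; returns the final p.
build_mei_insert <- function(s, p, db, d) {
  body <- if (!is.null(d$body_override)) d$body_override else
    family_body(db, d$family)
  if (d$trunc5 > 0) body <- substr(body, d$trunc5 + 1L, nchar(body))
  if (d$twin > 0) {
    body <- paste0(revcomp(substr(body, 1L, d$twin)),
                   substr(body, d$twin + 1L, nchar(body)))
  }
  td_truth <- list(side = NA_character_, start = NA_integer_,
                   end = NA_integer_)
  if (identical(d$td_side, "3p")) {
    seg <- d$td_seq
    body <- paste0(body, strrep("A", d$tail_len), seg)
    td_truth <- list(side = "3p", start = d$td_start, end = d$td_end)
  } else if (identical(d$td_side, "5p")) {
    body <- paste0(d$td_seq, body)
    td_truth <- list(side = "5p", start = d$td_start, end = d$td_end)
  }
  unit <- paste0(body, strrep("A", d$tail_len))
  if (identical(d$orientation, "-")) unit <- revcomp(unit)

  for (try in 1:40) {
    k <- d$tsd_len
    if (identical(d$tsd_end, "5p")) {
      # TSD copy downstream of p; insert starts with it
      tsd <- substr(s, p + 1L, p + k)
      insert <- paste0(tsd, unit)
      ok <- substr(insert, k + 1L, k + 1L) != base_at(s, p + k + 1L) &&
        lcs_len(insert, substr(s, p - 100L, p)) < k &&
        !grepl("N", tsd, fixed = TRUE)
    } else {
      # TSD copy upstream of p; insert ends with it
      tsd <- substr(s, p - k + 1L, p)
      insert <- paste0(unit, tsd)
      ni <- nchar(insert)
      ok <- substr(insert, ni - k, ni - k) != base_at(s, p - k) &&
        lcp_len(insert, substr(s, p + 1L, p + 100L)) < k &&
        !grepl("N", tsd, fixed = TRUE)
    }
    if (ok) {
      return(list(insert = insert, p = p, tsd = tsd, td = td_truth))
    }
    p <- p + 7L
  }
  stop("could not place MEI descriptor without ambiguity")
}

# Would a pure poly(A) tail of length tail_len appended after seq stay the
# maximal qualifying tract? Checks every window extending left into seq.
tail_stays_maximal <- function(seq, tail_len, min_purity = 0.90,
                               probe = 200L) {
  n <- nchar(seq)
  sfx <- rev(utf8ToInt(substr(seq, max(1L, n - probe + 1L), n)) ==
               utf8ToInt("A"))
  a <- cumsum(sfx)
  s <- seq_along(sfx)
  all((tail_len + a) / (tail_len + s) < min_purity | !sfx)
}

# sample a transduced segment from the genome, guarded against internal
# poly(A/T) tracts; when a tail of tail_len will be appended after the
# segment, the segment suffix must keep that tail maximal
sample_td_segment <- function(s, len, avoid, spacing = 12000,
                              tail_len = NULL) {
  n <- nchar(s)
  for (try in 1:200) {
    st <- sample.int(n - len - 2000L, 1) + 1000L
    if (any(abs(st - avoid) < spacing)) next
    seg <- substr(s, st + 1L, st + len)
    if (grepl("N", seg, fixed = TRUE)) next
    if (nrow(poly_tracts(seg, "A")) > 0) next
    if (nrow(poly_tracts(seg, "T")) > 0) next
    if (!is.null(tail_len) && !tail_stays_maximal(seg, tail_len)) next
    return(list(seq = seg, start = st, end = st + len))
  }
  stop("could not sample a transduced segment")
}

# mutate a sequence to a target identity by spaced substitutions
mutate_to_identity <- function(seq, identity) {
  n <- nchar(seq)
  nmut <- round((1 - identity) * n)
  if (nmut == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  at <- sort(sample.int(n, nmut))
  ch[at] <- vapply(ch[at], other_base, character(1))
  paste(ch, collapse = "")
}

#' Implant ground-truth SVs into a genome
#'
#' Takes a list of SV descriptors, modifies the genome where the
#' construction requires it (homology arms, microhomology seeds), and emits
#' the callset, a truth table and matching annotation tracks. Descriptor
#' types and their fields:
#'
#' * `mei`: `family` (Alu/L1/SVA), `tsd_len`, `tail_len`, `orientation`,
#'   `trunc5` (bp), `twin` (bp of 5' inversion), `td_side`
#'   (NA/"3p"/"5p"), `td_len`.
#' * `noncanonical_mei`: `family`, `flavor`
#'   ("no_polyA"/"truncated_3p"/"internal_rearrangement").
#' * `pseudogene`: `n_exons`, `exon_len`; exon copies also enter the exon
#'   track.
#' * `orphan`: `td_len` (transduced sequence + tail + TSD, no element).
#' * `vntr`: `motifs` (character vector), `copies` (same length),
#'   `filler` (bp of random padding).
#' * `dup`: `dup_class` ("tandem"/"inverted"/"complex"), `dup_len`.
#' * `numt`: `mt_start`, `mt_len` (may wrap the circular origin).
#' * `erv`: `erv_class` ("solo_LTR"/"ERVK").
#' * `del_repeat_pair`: `arm_len`, `arm_identity`, `del_len`, `track_mode`
#'   ("same_class"/"mismatch"/"none"), `track_class`, `sd` (logical).
#' * `del_blunt`: `del_len`.
#' * `del_micro`: `del_len`, `micro` (bp).
#'
#' @param genome Single-contig genome (named character vector).
#' @param descriptors List of descriptor lists (see above).
#' @param seed Integer seed.
#' @param db `sv_consensus_db` (required for element descriptors).
#' @return List: `genome` (modified), `records` (`sv_records`), `truth`
#'   (data.frame), `tracks` (list of `repeats`, `sd`, `exons` data.frames).
#' @export
implant_truth_svs <- function(genome, descriptors, seed = 1, db = NULL) {
  with_seed(seed, {
    chrom <- names(genome)[1]
    s <- genome[[chrom]]
    n <- length(descriptors)
    sites <- pick_sites(nchar(s), n)
    repeats <- list(); sds <- list(); exons <- list()
    rows <- list(); truth <- list()
    mito <- if (!is.null(db)) db$seqs[db$meta$name[db$meta$family == "MT"][1]] else NULL

    # phase 1: genome modifications for deletion constructs
    for (i in seq_len(n)) {
      d <- descriptors[[i]]
      p <- sites[i]
      if (identical(d$type, "del_repeat_pair")) {
        arm <- strip_tracts(random_dna(d$arm_len, 0.45))
        arm2 <- mutate_to_identity(arm, d$arm_identity)
        a <- p; b <- p + d$del_len
        substr(s, a + 1L, a + d$arm_len) <- arm
        substr(s, b + 1L, b + d$arm_len) <- arm2
        # keep the junction microhomology from spilling over the arms
        if (base_at(s, a) == base_at(s, b)) {
          s <- set_base(s, b, other_base(base_at(s, a)))
        }
        descriptors[[i]]$.a <- a
        descriptors[[i]]$.b <- b
      } else if (identical(d$type, "del_blunt")) {
        a <- p; b <- p + d$del_len
        if (base_at(s, a + 1L) == base_at(s, b + 1L)) {
          s <- set_base(s, b + 1L, other_base(base_at(s, a + 1L)))
        }
        if (base_at(s, a) == base_at(s, b)) {
          s <- set_base(s, b, other_base(base_at(s, a)))
        }
        descriptors[[i]]$.a <- a
        descriptors[[i]]$.b <- b
      } else if (identical(d$type, "del_micro")) {
        a <- p; b <- p + d$del_len
        m <- d$micro
        substr(s, b + 1L, b + m) <- substr(s, a + 1L, a + m)
        if (base_at(s, a + m + 1L) == base_at(s, b + m + 1L)) {
          s <- set_base(s, b + m + 1L, other_base(base_at(s, a + m + 1L)))
        }
        if (base_at(s, a) == base_at(s, b)) {
          s <- set_base(s, b, other_base(base_at(s, a)))
        }
        descriptors[[i]]$.a <- a
        descriptors[[i]]$.b <- b
      }
    }

    # phase 2: records from the final genome
    for (i in seq_len(n)) {
      d <- descriptors[[i]]
      p <- sites[i]
      id <- sprintf("sv%03d", i)
      tr <- list(id = id, type = d$type, class = NA_character_,
                 family = NA_character_, tsd_len = NA_integer_,
                 tail_len = NA_integer_, td_side = NA_character_,
                 td_start = NA_integer_, td_end = NA_integer_,
                 orientation = NA_character_, twin = FALSE,
                 motif = NA_character_, dup_class = NA_character_,
                 arm_len = NA_integer_, micro = NA_integer_,
                 mechanism = NA_character_, flags = NA_character_,
                 start = NA_integer_)

      if (identical(d$type, "mei") || identical(d$type, "pseudogene") ||
          identical(d$type, "orphan")) {
        if (identical(d$type, "mei")) {
          if (identical(d$td_side, "3p") || identical(d$td_side, "5p")) {
            seg <- sample_td_segment(
              s, d$td_len, sites,
              tail_len = if (identical(d$td_side, "3p")) d$tail_len else NULL
            )
            d$td_seq <- seg$seq; d$td_start <- seg$start; d$td_end <- seg$end
          }
          built <- build_mei_insert(s, p, db, d)
          tr$class <- if (identical(d$td_side, "3p")) "partnered_td_3p"
          else if (identical(d$td_side, "5p")) "partnered_td_5p"
          else paste0("solo_", d$family)
          tr$family <- d$family
          tr$orientation <- d$orientation
          tr$twin <- d$twin > 0
          tr$td_side <- built$td$side
          tr$td_start <- built$td$start
          tr$td_end <- built$td$end
        } else if (identical(d$type, "pseudogene")) {
          exs <- list()
          for (e in seq_len(d$n_exons)) {
            seg <- sample_td_segment(s, d$exon_len, sites,
                                     tail_len = d$tail_len)
            exs[[e]] <- seg
            exons[[length(exons) + 1L]] <- data.frame(
              chrom = chrom, start = seg$start, end = seg$end,
              id = sprintf("%s_exon%d", id, e), stringsAsFactors = FALSE
            )
          }
          d$body <- paste(vapply(exs, `[[`, character(1), "seq"),
                          collapse = "")
          built <- build_mei_insert(s, p, db, list(
            family = NA, trunc5 = 0, twin = 0, td_side = NA,
            tail_len = d$tail_len, orientation = "+", tsd_len = d$tsd_len,
            tsd_end = d$tsd_end, body_override = d$body
          ))
          tr$class <- "processed_pseudogene"
        } else {
          seg <- sample_td_segment(s, d$td_len, sites, tail_len = d$tail_len)
          built <- build_mei_insert(s, p, db, list(
            family = NA, trunc5 = 0, twin = 0, td_side = NA,
            tail_len = d$tail_len, orientation = "+", tsd_len = d$tsd_len,
            tsd_end = d$tsd_end, body_override = seg$seq
          ))
          tr$class <- "orphan_td"
          tr$td_side <- "orphan"
          tr$td_start <- seg$start; tr$td_end <- seg$end
        }
        p <- built$p
        tr$tsd_len <- d$tsd_len
        tr$tail_len <- d$tail_len
        anchor <- base_at(s, p)
        rows[[length(rows) + 1L]] <- list(
          id = id, start = p - 1L, ref = anchor,
          alt = paste0(anchor, built$insert)
        )
        tr$start <- p - 1L
      } else if (identical(d$type, "noncanonical_mei")) {
        body <- family_body(db, d$family)
        flags <- d$flavor
        if (identical(d$flavor, "no_polyA")) {
          insert <- body
        } else if (identical(d$flavor, "truncated_3p")) {
          insert <- paste0(substr(body, 1L, nchar(body) - 120L),
                           strrep("A", 15L))
        } else {
          third <- nchar(body) %/% 3L
          insert <- paste0(substr(body, 2L * third, nchar(body) - 100L),
                           substr(body, 1L, third), strrep("A", 15L))
        }
        tr$class <- "non_canonical_MEI"
        tr$family <- d$family
        tr$flags <- d$flavor
        anchor <- base_at(s, p)
        rows[[length(rows) + 1L]] <- list(
          id = id, start = p - 1L, ref = anchor,
          alt = paste0(anchor, insert)
        )
        tr$start <- p - 1L
      } else if (identical(d$type, "vntr")) {
        parts <- mapply(function(m, c) strrep(m, c), d$motifs, d$copies)
        filler <- if (!is.null(d$filler) && d$filler > 0)
          strip_tracts(random_dna(d$filler, 0.5)) else ""
        insert <- paste0(paste(parts, collapse = ""), filler)
        tr$class <- if (length(d$motifs) == 1) "VNTR_simple" else
          "VNTR_complex"
        tr$motif <- paste(vapply(d$motifs, canonical_rotation, character(1)),
                          collapse = ",")
        anchor <- base_at(s, p)
        rows[[length(rows) + 1L]] <- list(
          id = id, start = p - 1L, ref = anchor,
          alt = paste0(anchor, insert)
        )
        tr$start <- p - 1L
      } else if (identical(d$type, "dup")) {
        L <- d$dup_len
        src <- substr(s, p - L + 1L, p)
        insert <- switch(d$dup_class,
          tandem = src,
          inverted = revcomp(src),
          complex = paste0(substr(src, 1L, L %/% 2L),
                           revcomp(substr(src, L %/% 2L + 1L, L)))
        )
        tr$class <- paste0("DUP_", d$dup_class)
        tr$dup_class <- d$dup_class
        anchor <- base_at(s, p)
        rows[[length(rows) + 1L]] <- list(
          id = id, start = p - 1L, ref = anchor,
          alt = paste0(anchor, insert)
        )
        tr$start <- p - 1L
      } else if (identical(d$type, "numt")) {
        L <- nchar(mito)
        stopifnot(d$mt_start + d$mt_len <= 2L * L)
        insert <- substr(paste0(mito, mito), d$mt_start + 1L,
                         d$mt_start + d$mt_len)
        tr$class <- "NUMT"
        anchor <- base_at(s, p)
        rows[[length(rows) + 1L]] <- list(
          id = id, start = p - 1L, ref = anchor,
          alt = paste0(anchor, insert)
        )
        tr$start <- p - 1L
      } else if (identical(d$type, "erv")) {
        ltr <- db$seqs[["LTR5"]]
        insert <- if (identical(d$erv_class, "solo_LTR")) ltr else
          paste0(ltr, db$seqs[["ERVK_int"]], ltr)
        tr$class <- d$erv_class
        anchor <- base_at(s, p)
        rows[[length(rows) + 1L]] <- list(
          id = id, start = p - 1L, ref = anchor,
          alt = paste0(anchor, insert)
        )
        tr$start <- p - 1L
      } else if (d$type %in% c("del_repeat_pair", "del_blunt", "del_micro")) {
        a <- d$.a; b <- d$.b
        ref <- substr(s, a, b)  # anchor at a (1-based a = 0-based a-1)
        rows[[length(rows) + 1L]] <- list(
          id = id, start = a - 1L, ref = ref, alt = base_at(s, a)
        )
        tr$start <- a - 1L
        if (identical(d$type, "del_repeat_pair")) {
          tr$class <- "repeat_pair_deletion"
          tr$arm_len <- d$arm_len
          tr$mechanism <- if (d$arm_len >= 200) "NAHR" else if
            (d$arm_len >= 50) "HDR" else if (d$arm_len >= 16)
              "homology_independent" else "NHEJ_altEJ_MMBIR"
          mode <- if (is.null(d$track_mode)) "same_class" else d$track_mode
          cls <- if (is.null(d$track_class)) "AluSyn" else d$track_class
          if (mode == "same_class") {
            repeats[[length(repeats) + 1L]] <- data.frame(
              chrom = chrom, start = a, end = a + d$arm_len,
              class = cls, name = paste0(id, "_armA"), stringsAsFactors = FALSE
            )
            repeats[[length(repeats) + 1L]] <- data.frame(
              chrom = chrom, start = b, end = b + d$arm_len,
              class = cls, name = paste0(id, "_armB"), stringsAsFactors = FALSE
            )
          } else if (mode == "mismatch") {
            repeats[[length(repeats) + 1L]] <- data.frame(
              chrom = chrom, start = a, end = a + d$arm_len,
              class = cls, name = paste0(id, "_armA"), stringsAsFactors = FALSE
            )
            repeats[[length(repeats) + 1L]] <- data.frame(
              chrom = chrom, start = b, end = b + d$arm_len,
              class = paste0(cls, "_other"), name = paste0(id, "_armB"),
              stringsAsFactors = FALSE
            )
          }
          if (isTRUE(d$sd)) {
            # padding scaled to the arm so the 50%-of-SD condition is
            # attainable for short homologous regions
            pad <- min(50L, d$arm_len %/% 5L)
            sds[[length(sds) + 1L]] <- data.frame(
              chrom = chrom, start = a - pad, end = a + d$arm_len + pad,
              name = paste0(id, "_sd"), stringsAsFactors = FALSE
            )
          }
        } else if (identical(d$type, "del_blunt")) {
          tr$class <- "blunt_deletion"
          tr$micro <- 0L
          tr$mechanism <- "blunt"
        } else {
          tr$class <- "micro_deletion"
          tr$micro <- d$micro
          tr$mechanism <- if (d$micro >= 200) "NAHR" else
            if (d$micro >= 50) "HDR" else
              if (d$micro >= 16) "homology_independent" else
                "NHEJ_altEJ_MMBIR"
        }
      } else {
        stop("unknown descriptor type: ", d$type)
      }
      truth[[length(truth) + 1L]] <- tr
    }

    genome[[chrom]] <- s
    recs <- sv_records(
      id = vapply(rows, `[[`, character(1), "id"),
      chrom = chrom,
      start = vapply(rows, function(r) as.integer(r$start), integer(1)),
      ref = vapply(rows, `[[`, character(1), "ref"),
      alt = vapply(rows, `[[`, character(1), "alt")
    )
    truth_df <- do.call(rbind, lapply(truth, function(t) {
      as.data.frame(t, stringsAsFactors = FALSE)
    }))
    bind_track <- function(lst, cols) {
      if (length(lst)) do.call(rbind, lst) else
        setNames(as.data.frame(replicate(length(cols),
                                         character(0), simplify = FALSE)),
                 cols)
    }
    list(
      genome = genome, records = recs, truth = truth_df,
      tracks = list(
        repeats = bind_track(repeats, c("chrom", "start", "end", "class",
                                        "name")),
        sd = bind_track(sds, c("chrom", "start", "end", "name")),
        exons = bind_track(exons, c("chrom", "start", "end", "id"))
      )
    )
  })
}

#' Simulate a haplotype panel for the recurrence screen
#'
#' Two divergent ancestral haplotype cores are generated; each haplotype
#' copies one core and receives a Poisson number of private mutations. The
#' focal deletion is planted on `n_origins` distinct backgrounds: with one
#' origin every core-1 haplotype carries it; with two origins half of each
#' core carries it (allele frequency 0.5 in both cases, matching the
#' screen's 40-60% band).
#'
#' @param n_haplotypes Number of haplotypes.
#' @param n_snps SNP columns in the 100-kb window.
#' @param window Window width (bp).
#' @param del_len Deletion length (bp).
#' @param n_origins 1 or 2 independent origins.
#' @param mut_rate Expected private mutations per haplotype.
#' @param recomb_rate Per-haplotype probability of one core-switching
#'   crossover.
#' @param seed Integer seed.
#' @return List with `panel` (`sv_hap_panel`) and `truth` (list with
#'   `recurrent`, `origin` per haplotype).
#' @export
simulate_recurrence_panel <- function(n_haplotypes = 200, n_snps = 200,
                                      window = 100000, del_len = 800,
                                      n_origins = 1, mut_rate = 1,
                                      recomb_rate = 0, seed = 1) {
  stopifnot(n_origins %in% c(1L, 2L))
  with_seed(seed, {
    mid <- window %/% 2L
    del_start <- mid - del_len %/% 2L
    del_end <- del_start + del_len
    pos <- sort(sample(setdiff(0:window, del_start:(del_end - 1L)), n_snps))
    core <- rbind(rbinom(n_snps, 1, 0.5), rbinom(n_snps, 1, 0.5))
    origin <- rep(1:2, length.out = n_haplotypes)
    mat <- core[origin, , drop = FALSE]
    for (h in seq_len(n_haplotypes)) {
      if (recomb_rate > 0 && runif(1) < recomb_rate) {
        cut <- sample.int(n_snps - 1L, 1)
        mat[h, (cut + 1L):n_snps] <- core[3L - origin[h], (cut + 1L):n_snps]
      }
      nm <- rpois(1, mut_rate)
      if (nm > 0) {
        at <- sample.int(n_snps, min(nm, n_snps))
        mat[h, at] <- 1L - mat[h, at]
      }
    }
    del_state <- integer(n_haplotypes)
    if (n_origins == 1) {
      del_state[origin == 1] <- 1L
    } else {
      for (o in 1:2) {
        idx <- which(origin == o)
        del_state[idx[seq_len(ceiling(length(idx) / 2))]] <- 1L
      }
    }
    list(
      panel = hap_panel(pos, mat, del_state, del_start, del_end),
      truth = list(recurrent = n_origins > 1, origin = origin)
    )
  })
}
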