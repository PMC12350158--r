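# Evaluation harness: each function generates a seeded truth set with the
# synthetic-fixture module, runs the corresponding annotator, and measures
# recovery against the truth (or against an independent reference
# implementation). Shared by the test suite and scripts/acceptance.R.

mei_mix_descriptors <- function(n, seed, db) {
  with_seed(seed, {
    fams <- sample(MEI_FAMILIES, n, replace = TRUE)
    cat_u <- runif(n)
    lapply(seq_len(n), function(i) {
      fam <- fams[i]
      body_len <- nchar(family_body(db, fam))
      d <- list(type = "mei", family = fam,
                tsd_len = sample(5:30, 1), tail_len = sample(10:40, 1),
                orientation = sample(c("+", "-"), 1),
                tsd_end = sample(c("5p", "3p"), 1),
                trunc5 = 0L, twin = 0L, td_side = NA, td_len = 0L)
      if (cat_u[i] < 0.15) {
        d$td_side <- "3p"; d$td_len <- sample(50:500, 1)
      } else if (cat_u[i] < 0.20) {
        d$td_side <- "5p"; d$td_len <- sample(50:500, 1)
      } else if (cat_u[i] < 0.35) {
        d$trunc5 <- sample.int(max(2L, floor(body_len * 0.4)), 1)
      } else if (cat_u[i] < 0.50) {
        d$twin <- sample(seq.int(50L, max(51L, floor(body_len * 0.3))), 1)
      }
      d
    })
  })
}

#' Canonical-MEI recovery on a seeded truth set
#'
#' Implants canonical mobile element insertions (Alu/L1/SVA mix, randomized
#' TSD 5-30 bp and poly(A) 10-40 bp, 30% with 5' truncation or inversion,
#' 20% with 50-500 bp transductions) into a random genome, annotates them,
#' and scores exact recovery of class, TSD length, tail length, transduction
#' side and source locus (overlap with the true donor interval).
#'
#' @param n Number of implants.
#' @param genome_len Genome length (bp).
#' @param seed Integer seed.
#' @return List with `recovery` (fraction fully recovered), `n`, and a
#'   per-record `details` data.frame.
#' @export
eval_mei_recovery <- function(n = 200, genome_len = 5e6, seed = 1) {
  genome <- simulate_genome(genome_len, seed = seed)
  db <- synthetic_consensus_db(seed + 1)
  desc <- mei_mix_descriptors(n, seed + 2, db)
  fx <- implant_truth_svs(genome, desc, seed = seed + 3, db = db)
  ann <- annotate_inserts(fx$records, fx$genome, db)
  m <- merge(fx$truth, ann, by = "id", suffixes = c(".t", ""))
  src_ok <- ifelse(
    is.na(m$td_side.t),
    is.na(m$td_side) | m$td_side == "orphan",
    !is.na(m$td_side) & m$td_side == m$td_side.t &
      !is.na(m$td_source_start) &
      pmin(m$td_end, m$td_source_end) > pmax(m$td_start, m$td_source_start)
  )
  ok <- m$class.t == m$class &
    m$tsd_len.t == m$tsd_len &
    m$tail_len.t == m$tail_len &
    src_ok
  list(recovery = mean(ok), n = nrow(m),
       details = data.frame(id = m$id, class_truth = m$class.t,
                            class = m$class, ok = ok,
                            stringsAsFactors = FALSE))
}

#' Solo-MEI false-positive count on random sequence
#'
#' @param n Number of random queries.
#' @param len Query length (bp).
#' @param seed Integer seed.
#' @return List with `n_solo` (solo calls), `n`.
#' @export
eval_random_solo <- function(n = 1000, len = 1000, seed = 1) {
  db <- synthetic_consensus_db(seed + 1)
  n_solo <- with_seed(seed, {
    count <- 0L
    for (i in seq_len(n)) {
      seq <- random_dna(len, 0.45)
      up <- random_dna(100, 0.45); down <- random_dna(100, 0.45)
      ann <- annotate_insert(seq, up, down, genome = NULL, db = db)
      if (startsWith(ann$class, "solo_")) count <- count + 1L
    }
    count
  })
  list(n_solo = n_solo, n = n)
}

#' L1 subfamily diagnostics on constructed cases
#'
#' Twelve constructed cores with planted diagnostic bases at consensus
#' positions 5929-5931 and 5535/5538, covering every branch of the rule
#' table (pre-Ta, Ta-0, Ta-1, Ta fallback, undetermined profiles, and
#' uncovered diagnostic positions).
#'
#' @param seed Integer seed (consensus construction).
#' @return List with `n_correct`, `n`, and the per-case table.
#' @export
eval_subfamily_cases <- function(seed = 1) {
  db <- synthetic_consensus_db(seed + 1)
  l1 <- db$seqs[["L1"]]
  make_core <- function(triplet, ta) {
    ch <- strsplit(l1, "")[[1]]
    ch[5929:5931] <- strsplit(triplet, "")[[1]]
    ch[c(5535, 5538)] <- ta
    paste(ch, collapse = "")
  }
  cases <- list(
    list(triplet = "ACG", ta = c("G", "C"), expect = "pre-Ta"),
    list(triplet = "ACG", ta = c("T", "G"), expect = "pre-Ta"),
    list(triplet = "ACA", ta = c("G", "C"), expect = "Ta-0"),
    list(triplet = "ACA", ta = c("T", "G"), expect = "Ta-1"),
    list(triplet = "ACA", ta = c("A", "C"), expect = "Ta"),
    list(triplet = "ACA", ta = c("G", "G"), expect = "Ta"),
    list(triplet = "ACA", ta = c("T", "C"), expect = "Ta"),
    list(triplet = "ACC", ta = c("G", "C"), expect = "undetermined"),
    list(triplet = "AAA", ta = c("T", "G"), expect = "undetermined"),
    list(triplet = "GCG", ta = c("G", "C"), expect = "undetermined"),
    list(triplet = "ACT", ta = c("T", "G"), expect = "undetermined"),
    list(truncated = TRUE, expect = "undetermined")
  )
  res <- vapply(cases, function(cs) {
    core <- if (isTRUE(cs$truncated)) substr(l1, 1L, 5000L) else
      make_core(cs$triplet, cs$ta)
    chain <- decompose_insert(core, db)
    l1_subfamily(chain, core, db)
  }, character(1))
  expect <- vapply(cases, `[[`, character(1), "expect")
  list(n_correct = sum(res == expect), n = length(cases),
       table = data.frame(expected = expect, got = res,
                          stringsAsFactors = FALSE))
}

#' Microhomology oracle equivalence on simulated SVs
#'
#' Simulates deletions and insertions (half at positions seeded with exact
#' junction repeats of 1-80 bp, exercising the 50-bp cap) and compares the
#' vectorized microhomology measurement with the character-loop reference.
#'
#' @param n Number of simulated SVs.
#' @param genome_len Genome length (bp).
#' @param seed Integer seed.
#' @return List with `agreement` (fraction equal), `n`, `max_diff`.
#' @export
eval_microhomology_oracle <- function(n = 10000, genome_len = 2e6, seed = 1) {
  genome <- simulate_genome(genome_len, seed = seed)
  with_seed(seed + 1, {
    chrom <- names(genome)[1]
    s <- genome[[chrom]]
    # seed exact junction repeats at spaced positions
    n_seeded <- min(n %/% 2L, 2000L)
    seed_pos <- 50000L + (seq_len(n_seeded) - 1L) * 600L
    seed_m <- sample(1:80, n_seeded, replace = TRUE)
    seed_del <- sample(60:400, n_seeded, replace = TRUE)
    ch <- strsplit(s, "")[[1]]
    for (k in seq_len(n_seeded)) {
      a <- seed_pos[k]; b <- a + seed_del[k]; m <- seed_m[k]
      ch[(b + 1L):(b + m)] <- ch[(a + 1L):(a + m)]
    }
    s <- paste(ch, collapse = "")
    genome[[chrom]] <- s
    recs <- list()
    for (i in seq_len(n)) {
      if (i <= n_seeded) {
        a <- seed_pos[i]; L <- seed_del[i]
        recs[[i]] <- list(start = a - 1L, ref = substr(s, a, a + L),
                          alt = substr(s, a, a), type = "DEL")
      } else if (i %% 2 == 0) {
        a <- sample.int(nchar(s) - 10000L, 1) + 5000L
        L <- sample(50:400, 1)
        recs[[i]] <- list(start = a - 1L, ref = substr(s, a, a + L),
                          alt = substr(s, a, a), type = "DEL")
      } else {
        a <- sample.int(nchar(s) - 10000L, 1) + 5000L
        L <- sample(50:400, 1)
        # half the insertions start with a copy of the downstream flank
        ins <- if (i %% 4 == 1) {
          paste0(substr(s, a + 1L, a + sample(1:80, 1)), random_dna(L, 0.45))
        } else {
          random_dna(L, 0.45)
        }
        recs[[i]] <- list(start = a - 1L, ref = substr(s, a, a),
                          alt = paste0(substr(s, a, a), ins), type = "INS")
      }
    }
    rec_df <- sv_records(
      id = sprintf("mh%05d", seq_len(n)), chrom = chrom,
      start = vapply(recs, function(r) as.integer(r$start), integer(1)),
      ref = vapply(recs, `[[`, character(1), "ref"),
      alt = vapply(recs, `[[`, character(1), "alt")
    )
    fast <- integer(n); naive <- integer(n)
    rec_list <- lapply(seq_len(n), function(i) as.list(rec_df[i, ]))
    for (i in seq_len(n)) {
      fast[i] <- microhomology_len(rec_list[[i]], genome)
      naive[i] <- microhomology_len_naive(rec_list[[i]], genome)
    }
    list(agreement = mean(fast == naive), n = n,
         max_diff = max(abs(fast - naive)))
  })
}

#' Homology-scan recovery and mechanism routing on planted constructs
#'
#' Plants repeat-pair-mediated deletions (arm lengths 100 bp - 5 kb,
#' identities 0.85-1.0), blunt deletions and microhomology deletions,
#' annotates their junctions and scores homology-length recovery (within
#' 10%), mechanism-bin routing, and repeat/SD mediation against the
#' synthetic annotation tracks.
#'
#' @param seed Integer seed.
#' @param genome_len Genome length (bp).
#' @return List with `len_recovery`, `mech_accuracy`, `mediation_accuracy`,
#'   `n`, `details`.
#' @export
eval_homology_scan <- function(seed = 1, genome_len = 2e6) {
  genome <- simulate_genome(genome_len, seed = seed)
  arm_lens <- rep(c(100L, 150L, 250L, 400L, 800L, 1500L, 3000L, 5000L), 3)
  desc <- with_seed(seed + 1, {
    idents <- sample(c(1, 1, 0.95, 0.9, 0.85), length(arm_lens),
                     replace = TRUE)
    track_mode <- rep(c("same_class", "mismatch", "none"),
                      length.out = length(arm_lens))
    sdflag <- rep(c(FALSE, FALSE, TRUE), length.out = length(arm_lens))
    c(
      lapply(seq_along(arm_lens), function(i) {
        list(type = "del_repeat_pair", arm_len = arm_lens[i],
             arm_identity = idents[i],
             del_len = arm_lens[i] + sample(100:500, 1),
             track_mode = track_mode[i], sd = sdflag[i])
      }),
      lapply(1:6, function(i) list(type = "del_blunt",
                                   del_len = sample(100:800, 1))),
      lapply(1:6, function(i) list(type = "del_micro",
                                   del_len = sample(100:800, 1),
                                   micro = sample(1:15, 1))),
      lapply(1:6, function(i) list(type = "del_micro",
                                   del_len = sample(100:800, 1),
                                   micro = sample(16:45, 1)))
    )
  })
  fx <- implant_truth_svs(genome, desc, seed = seed + 2)
  jc <- annotate_junctions(fx$records, fx$genome,
                           repeat_track = fx$tracks$repeats,
                           sd_track = fx$tracks$sd)
  m <- merge(fx$truth, jc, by = "id")
  is_arm <- m$type == "del_repeat_pair"
  len_ok <- abs(m$hom_len[is_arm] - m$arm_len[is_arm]) <=
    0.10 * m$arm_len[is_arm]
  mech_ok <- m$mechanism.x == m$mechanism.y
  med_expect <- is_arm &
    vapply(seq_len(nrow(m)), function(i) {
      d <- desc[[match(m$id[i], fx$truth$id)]]
      identical(d$track_mode, "same_class")
    }, logical(1))
  med_ok <- (!is.na(m$mediating_repeat)) == med_expect
  sd_expect <- vapply(seq_len(nrow(m)), function(i) {
    d <- desc[[match(m$id[i], fx$truth$id)]]
    isTRUE(d$sd)
  }, logical(1))
  sd_ok <- m$sd_mediated == sd_expect
  list(len_recovery = mean(len_ok), mech_accuracy = mean(mech_ok),
       mediation_accuracy = mean(med_ok & sd_ok), n = nrow(m),
       details = m)
}

#' VNTR and duplication rule accuracy on a constructed truth set
#'
#' @param n Number of constructs (mixed simple/complex VNTRs and tandem/
#'   inverted/complex duplications).
#' @param seed Integer seed.
#' @param genome_len Genome length (bp).
#' @return List with `accuracy`, `n`, `details`.
#' @export
eval_vntr_dup <- function(n = 100, seed = 1, genome_len = 2.5e6) {
  genome <- simulate_genome(genome_len, seed = seed)
  db <- synthetic_consensus_db(seed + 1)
  desc <- with_seed(seed + 2, {
    lapply(seq_len(n), function(i) {
      u <- (i - 1) / n
      if (u < 0.4) {
        motif <- strip_tracts(random_dna(sample(2:8, 1), 0.5), min_len = 5)
        list(type = "vntr", motifs = motif,
             copies = sample(20:60, 1), filler = 0L)
      } else if (u < 0.7) {
        m1 <- strip_tracts(random_dna(sample(3:8, 1), 0.5), min_len = 5)
        m2 <- strip_tracts(random_dna(sample(3:8, 1), 0.5), min_len = 5)
        total <- 300L
        c1 <- max(2L, round(0.5 * total / nchar(m1)))
        c2 <- max(2L, round(0.4 * total / nchar(m2)))
        list(type = "vntr", motifs = c(m1, m2), copies = c(c1, c2),
             filler = 30L)
      } else if (u < 0.85) {
        list(type = "dup", dup_class = "tandem", dup_len = sample(200:600, 1))
      } else if (u < 0.95) {
        list(type = "dup", dup_class = "inverted",
             dup_len = sample(200:600, 1))
      } else {
        list(type = "dup", dup_class = "complex", dup_len = sample(300:600, 1))
      }
    })
  })
  fx <- implant_truth_svs(genome, desc, seed = seed + 3, db = db)
  ann <- annotate_sv_callset(fx$records, fx$genome, db)
  m <- merge(fx$truth, ann, by = "id", suffixes = c(".t", ""))
  ok <- m$class.t == m$class
  list(accuracy = mean(ok), n = nrow(m),
       details = data.frame(id = m$id, truth = m$class.t, got = m$class,
                            ok = ok, stringsAsFactors = FALSE))
}

#' Chaining optimality against exhaustive search
#'
#' @param n Number of random instances (each with at most `max_hits` hits).
#' @param max_hits Maximum hits per instance.
#' @param seed Integer seed.
#' @return List with `agreement` (fraction of instances where the dynamic
#'   program matches the exhaustive optimum on coverage, hit count and
#'   score), `n`.
#' @export
eval_chain_optimality <- function(n = 1000, max_hits = 12, seed = 1) {
  with_seed(seed, {
    ok <- logical(n)
    for (i in seq_len(n)) {
      k <- sample.int(max_hits, 1)
      qs <- sample(0:180, k, replace = TRUE)
      len <- sample(5:80, k, replace = TRUE)
      hits <- data.frame(query_start = qs, query_end = qs + len,
                         target = "t", target_start = qs,
                         target_end = qs + len, strand = "+",
                         length = len, matches = len, identity = 1,
                         score = sample(5:100, k, replace = TRUE),
                         uniqueness = Inf)
      a <- chain_best(hits, 260L)
      b <- chain_best_exhaustive(hits, 260L)
      ok[i] <- a$covered_bases == b$covered_bases &&
        nrow(a$hits) == nrow(b$hits) &&
        sum(a$hits$score) == sum(b$hits$score)
    }
    list(agreement = mean(ok), n = n)
  })
}

#' Separation of biased and balanced transduction sources
#'
#' Each replicate draws a 90%-3' biased source and a balanced source (40
#' transductions each), runs the binomial bias test with BH adjustment, and
#' counts a success when the biased locus is flagged and the balanced one is
#' not.
#'
#' @param reps Number of replicates.
#' @param n_per_locus Transductions per source.
#' @param seed Integer seed.
#' @return List with `separation` (success fraction), `reps`.
#' @export
eval_bias_separation <- function(reps = 200, n_per_locus = 40, seed = 1) {
  with_seed(seed, {
    ok <- logical(reps)
    for (r in seq_len(reps)) {
      n3_biased <- rbinom(1, n_per_locus, 0.9)
      n3_bal <- rbinom(1, n_per_locus, 0.5)
      loci <- data.frame(
        n_5p = c(n_per_locus - n3_biased, n_per_locus - n3_bal),
        n_3p = c(n3_biased, n3_bal)
      )
      res <- bias_test(loci)
      ok[r] <- res$bias[1] == "3p" && res$bias[2] == "none"
    }
    list(separation = mean(ok), reps = reps)
  })
}

#' Recurrence screen specificity and sensitivity
#'
#' Single-origin panels must never yield a supported verdict; dual-origin
#' panels at 200 haplotypes should be supported in at least 95% of
#' replicates.
#'
#' @param n_single,n_dual Replicate counts.
#' @param seed Integer seed.
#' @return List with `single_supported` (fraction, specificity complement),
#'   `dual_supported` (sensitivity), replicate counts.
#' @export
eval_recurrence_screen <- function(n_single = 1000, n_dual = 100, seed = 1) {
  single <- vapply(seq_len(n_single), function(r) {
    sim <- simulate_recurrence_panel(n_haplotypes = 60, n_snps = 100,
                                     n_origins = 1, seed = seed + r)
    assess_recurrence(sim$panel)$verdict == "supported"
  }, logical(1))
  dual <- vapply(seq_len(n_dual), function(r) {
    sim <- simulate_recurrence_panel(n_haplotypes = 200, n_snps = 200,
                                     n_origins = 2, seed = seed + 5000 + r)
    assess_recurrence(sim$panel)$verdict == "supported"
  }, logical(1))
  list(single_supported = mean(single), dual_supported = mean(dual),
       n_single = n_single, n_dual = n_dual)
}

# reference pairwise duplicate marking: full O(n^2) rule evaluation,
# transitive closure by boolean matrix expansion
mark_duplicate_sites_naive <- function(records, max_offset = 500,
                                       min_size_ratio = 0.5,
                                       max_divergence = 0.30,
                                       min_carrier_frac = 0.10) {
  n <- nrow(records)
  adj <- diag(n) > 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      adj[i, j] <- sv_pair_rules(records[i, ], records[j, ], max_offset,
                                 min_size_ratio, max_divergence,
                                 min_carrier_frac, ratio_strict = TRUE)
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0 | adj
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  grp <- integer(n)
  g <- 0L
  for (i in seq_len(n)) {
    if (grp[i] == 0L) { g <- g + 1L; grp[adj[i, ]] <- g }
  }
  dup <- logical(n)
  for (k in unique(grp)) {
    idx <- which(grp == k)
    if (length(idx) == 1) next
    o <- idx[order(records$start[idx], -records$svlen[idx], records$id[idx])]
    dup[setdiff(idx, o[1])] <- TRUE
  }
  list(group = grp, duplicate = dup)
}

#' Duplicate-marking and matching agreement with the pairwise oracle
#'
#' Generates random callsets (with planted duplicates and boundary cases at
#' the offset and size-ratio thresholds) and compares
#' [mark_duplicate_sites()] and [match_callsets()] against exhaustive
#' pairwise rule evaluation.
#'
#' @param n_callsets Number of random callsets.
#' @param seed Integer seed.
#' @return List with `dedup_agreement`, `match_agreement` (fractions of
#'   callsets in exact agreement), `n`.
#' @export
eval_dedup_match <- function(n_callsets = 1000, seed = 1) {
  with_seed(seed, {
    dedup_ok <- logical(n_callsets)
    match_ok <- logical(n_callsets)
    for (cc in seq_len(n_callsets)) {
      n0 <- sample(4:10, 1)
      starts <- sort(sample.int(100000L, n0))
      lens <- sample(c(45L, 50L, 60L, 79L, 80L, 100L, 150L), n0,
                     replace = TRUE)
      alleles <- vapply(lens, function(L) random_dna(L, 0.45), character(1))
      ids <- sprintf("c%d_%02d", cc, seq_len(n0))
      # planted near-duplicates at and around the rule boundaries
      extra <- sample.int(n0, sample(1:3, 1))
      st2 <- starts[extra] + sample(c(0L, 50L, 60L, 499L, 500L, 501L, 600L),
                                    length(extra), replace = TRUE)
      al2 <- alleles[extra]
      ratio_jitter <- sample(c(1, 1, 0.79, 0.5, 0.45), length(extra),
                             replace = TRUE)
      l2 <- pmax(10L, as.integer(round(lens[extra] * ratio_jitter)))
      al2 <- vapply(seq_along(extra), function(k) {
        if (l2[k] == lens[extra[k]]) al2[k] else
          substr(paste0(al2[k], random_dna(200, 0.45)), 1L, l2[k])
      }, character(1))
      all_starts <- c(starts, st2)
      all_alleles <- c(alleles, al2)
      all_ids <- c(ids, sprintf("c%d_x%02d", cc, seq_along(extra)))
      anchor <- "C"
      recs <- sv_records(
        id = all_ids, chrom = "chr1", start = all_starts,
        ref = anchor, alt = paste0(anchor, all_alleles)
      )
      recs <- recs[order(recs$start, recs$id), ]
      marked <- mark_duplicate_sites(recs)
      ref <- mark_duplicate_sites_naive(recs)
      same_part <- all(outer(marked$dup_group, marked$dup_group, "==") ==
                         outer(ref$group, ref$group, "=="))
      dedup_ok[cc] <- same_part && identical(marked$duplicate, ref$duplicate)
      # matching against a shifted copy of the callset
      comp <- recs
      comp$id <- paste0(comp$id, "_c")
      shift <- sample(c(0L, 50L, 51L, 60L), nrow(comp), replace = TRUE)
      comp$start <- comp$start + shift
      comp$end <- comp$end + shift
      mres <- match_callsets(recs, comp)
      naive_matched <- vapply(seq_len(nrow(recs)), function(i) {
        any(vapply(seq_len(nrow(comp)), function(j) {
          sv_pair_rules(recs[i, ], comp[j, ], 50, 0.8, 0.10, NULL)
        }, logical(1)))
      }, logical(1))
      match_ok[cc] <- identical(mres$base$matched, naive_matched)
    }
    list(dedup_agreement = mean(dedup_ok), match_agreement = mean(match_ok),
         n = n_callsets)
  })
}

#' Pseudo-haplotype construction properties on random callsets
#'
#' Checks that the group count equals the sweep-line maximum overlap depth
#' and that implantation round trips exactly (each implanted allele is
#' recovered through the coordinate map).
#'
#' @param n_callsets Number of random callsets.
#' @param seed Integer seed.
#' @return List with `depth_agreement`, `roundtrip_ok` (fractions), `n`.
#' @export
eval_pseudohap <- function(n_callsets = 1000, seed = 1) {
  with_seed(seed, {
    depth_ok <- logical(n_callsets)
    rt_ok <- logical(n_callsets)
    for (cc in seq_len(n_callsets)) {
      glen <- 60000L
      genome <- setNames(random_dna(glen, 0.41), "chrS")
      nrec <- sample(3:12, 1)
      start <- sort(sample.int(glen - 2000L, nrec))
      rows <- lapply(seq_len(nrec), function(i) {
        if (runif(1) < 0.5) {
          L <- sample(50:400, 1)
          list(start = start[i],
               ref = substr(genome[[1]], start[i] + 1L, start[i] + L + 1L),
               alt = substr(genome[[1]], start[i] + 1L, start[i] + 1L))
        } else {
          L <- sample(50:300, 1)
          anc <- substr(genome[[1]], start[i] + 1L, start[i] + 1L)
          list(start = start[i], ref = anc,
               alt = paste0(anc, random_dna(L, 0.45)))
        }
      })
      recs <- sv_records(
        id = sprintf("g%d_%02d", cc, seq_len(nrec)), chrom = "chrS",
        start = vapply(rows, function(r) as.integer(r$start), integer(1)),
        ref = vapply(rows, `[[`, character(1), "ref"),
        alt = vapply(rows, `[[`, character(1), "alt")
      )
      parts <- partition_nonoverlapping(recs)
      # sweep-line max depth oracle over the occupied intervals
      occ_s <- ifelse(parts$svtype == "INS", parts$start, parts$start)
      occ_e <- ifelse(parts$svtype == "INS", parts$start + 1L, parts$end)
      events <- rbind(data.frame(pos = occ_s, d = 1L),
                      data.frame(pos = occ_e, d = -1L))
      events <- events[order(events$pos, events$d), ]
      depth <- max(cumsum(events$d))
      depth_ok[cc] <- max(parts$group_id) == depth
      ok <- TRUE
      for (g in unique(parts$group_id)) {
        grp <- parts[parts$group_id == g, , drop = FALSE]
        ph <- implant_pseudohaplotype(genome, grp, g)
        for (i in seq_len(nrow(grp))) {
          pp <- pseudohap_pos(ph, "chrS", grp$start[i])
          got <- substr(ph$sequences[[1]], pp + 1L, pp + nchar(grp$alt[i]))
          if (!identical(got, grp$alt[i])) ok <- FALSE
        }
      }
      rt_ok[cc] <- ok
    }
    list(depth_agreement = mean(depth_ok), roundtrip_ok = mean(rt_ok),
         n = n_callsets)
  })
}
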