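# Breakpoint implantation, microhomology, windowed homology scan,
# mechanism binning and repeat/SD mediation.

test_that("insertion implantation shifts coordinates and round trips", {
  set.seed(51)
  g <- fixture_genome()
  pos <- 100000L
  anchor <- genome_seq(g, "chrS", pos, pos + 1)
  ins <- rdna(100)
  rec <- one_record("i1", "chrS", pos, anchor, paste0(anchor, ins))
  imp <- implant_allele(g, rec)
  expect_equal(nchar(imp$seq), nchar(g[["chrS"]]) + 100L)
  expect_equal(imp$br - imp$bl, 100L)
  # removing the implanted bases restores the original contig
  restored <- paste0(substr(imp$seq, 1, imp$bl),
                     substr(imp$seq, imp$br + 1, nchar(imp$seq)))
  expect_identical(restored, g[["chrS"]])
  # deletions need no modification
  del <- one_record("d1", "chrS", pos, genome_seq(g, "chrS", pos, pos + 61),
                    anchor)
  impd <- implant_allele(g, del)
  expect_identical(impd$seq, g[["chrS"]])
  expect_equal(impd$br - impd$bl, 60L)
})

test_that("microhomology equals brute-force extension and respects the cap", {
  set.seed(52)
  g <- fixture_genome()
  s <- g[["chrS"]]
  # plant an exact 6-bp junction repeat
  a <- 50000L; b <- 50200L
  substr(s, b + 1, b + 6) <- substr(s, a + 1, a + 6)
  if (substr(s, a + 7, a + 7) == substr(s, b + 7, b + 7)) {
    substr(s, b + 7, b + 7) <- setdiff(c("A", "C", "G", "T"),
                                       substr(s, a + 7, a + 7))[1]
  }
  if (substr(s, a, a) == substr(s, b, b)) {
    substr(s, b, b) <- setdiff(c("A", "C", "G", "T"), substr(s, a, a))[1]
  }
  g2 <- setNames(s, "chrS")
  del <- one_record("d1", "chrS", a - 1L, substr(s, a, b), substr(s, a, a))
  expect_equal(microhomology_len(del, g2), 6L)
  expect_equal(microhomology_len_naive(del, g2), 6L)
  # an 80-bp planted repeat reports the 50-bp cap
  s2 <- g[["chrS"]]
  substr(s2, b + 1, b + 80) <- substr(s2, a + 1, a + 80)
  g3 <- setNames(s2, "chrS")
  del2 <- one_record("d2", "chrS", a - 1L, substr(s2, a, b), substr(s2, a, a))
  expect_equal(microhomology_len(del2, g3), 50L)
  # random junctions agree with the oracle
  for (i in 1:200) {
    st <- sample(60000:300000, 1)
    L <- sample(50:300, 1)
    r <- one_record("x", "chrS", st,
                    genome_seq(g, "chrS", st, st + L + 1),
                    genome_seq(g, "chrS", st, st + 1))
    expect_equal(microhomology_len(r, g), microhomology_len_naive(r, g))
  }
})

test_that("homology scan recovers planted flanking repeats", {
  set.seed(53)
  genome <- simulate_genome(3e5, seed = 53)
  s <- genome[[1]]
  arm <- rdna(295)
  ch <- strsplit(arm, "")[[1]]
  at <- sample(295, 24)  # ~92% identity copy
  ch[at] <- vapply(ch[at], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  arm2 <- paste(ch, collapse = "")
  a <- 100000L; b <- 100800L
  substr(s, a + 1, a + 295) <- arm
  substr(s, b + 1, b + 295) <- arm2
  g <- setNames(s, "chrS")
  del <- one_record("d1", "chrS", a - 1L, substr(s, a, b), substr(s, a, a))
  sc <- homology_scan(del, g)
  expect_false(is.null(sc))
  expect_lt(abs(sc$length - 295) / 295, 0.1)
  expect_gte(sc$identity, 0.85)
  # arms are reported at the planted positions
  expect_lt(abs(sc$arm_left$start - a), 20)
  expect_lt(abs(sc$arm_right$start - b), 20)
  # random flanks yield nothing
  del2 <- one_record("d2", "chrS", 200000L,
                     genome_seq(g, "chrS", 200000, 200500),
                     genome_seq(g, "chrS", 200000, 200001))
  expect_null(homology_scan(del2, g))
})

test_that("mechanism bins partition homology lengths", {
  expect_equal(classify_mechanism(0), "blunt")
  expect_equal(classify_mechanism(1), "NHEJ_altEJ_MMBIR")
  expect_equal(classify_mechanism(14), "NHEJ_altEJ_MMBIR")
  expect_equal(classify_mechanism(16), "homology_independent")
  expect_equal(classify_mechanism(49), "homology_independent")
  expect_equal(classify_mechanism(50), "HDR")
  expect_equal(classify_mechanism(199), "HDR")
  expect_equal(classify_mechanism(300), "NAHR")
  expect_equal(classify_mechanism(300, excluded = TRUE), "unassigned")
  # every non-excluded SV gets exactly one label
  labs <- vapply(0:400, classify_mechanism, "")
  expect_false(any(is.na(labs)))
  expect_setequal(unique(labs), c("blunt", "NHEJ_altEJ_MMBIR",
                                  "homology_independent", "HDR", "NAHR"))
})

test_that("repeat and SD mediation follow the dual 85% rules", {
  call <- structure(list(
    sv_id = "d", hom_len = 295L, microhomology = 10L,
    scan = list(length = 295L, identity = 0.92,
                arm_left = list(chrom = "chrS", start = 1000L, end = 1295L),
                arm_right = list(chrom = "chrS", start = 2000L, end = 2295L)),
    hom_class = "homology_ge200", mechanism = "NAHR",
    mediating_repeat = NA_character_, sd_mediated = FALSE
  ), class = "sv_junction_call")
  track_same <- data.frame(chrom = "chrS", start = c(995L, 1995L),
                           end = c(1300L, 2300L), class = "Alu",
                           name = c("e1", "e2"))
  expect_equal(annotate_repeat_or_sd_mediated(call, track_same)$
                 mediating_repeat, "Alu")
  track_diff <- track_same
  track_diff$class <- c("Alu", "L1")
  expect_true(is.na(annotate_repeat_or_sd_mediated(call, track_diff)$
                      mediating_repeat))
  # covering both arms but spanning <85% of either element fails
  track_big <- data.frame(chrom = "chrS", start = c(0L, 1500L),
                          end = c(1400L, 3000L), class = "Alu",
                          name = c("b1", "b2"))
  expect_true(is.na(annotate_repeat_or_sd_mediated(call, track_big)$
                      mediating_repeat))
  # SD rule: >85% of the homologous region and >200 bp
  sd <- data.frame(chrom = "chrS", start = 980L, end = 1290L, name = "sd1")
  expect_true(annotate_repeat_or_sd_mediated(call, sd_track = sd)$sd_mediated)
  sd_small <- data.frame(chrom = "chrS", start = 1100L, end = 1250L,
                         name = "sd2")
  expect_false(annotate_repeat_or_sd_mediated(call, sd_track = sd_small)$
                 sd_mediated)
})

test_that("insertion junction analysis is consistent after implantation", {
  set.seed(54)
  g <- fixture_genome()
  pos <- 120000L
  anchor <- genome_seq(g, "chrS", pos, pos + 1)
  # insert starting with a copy of the downstream flank: microhomology
  ins <- paste0(genome_seq(g, "chrS", pos + 1, pos + 9), rdna(200))
  rec <- one_record("i1", "chrS", pos, anchor, paste0(anchor, ins))
  expect_equal(microhomology_len(rec, g), microhomology_len_naive(rec, g))
  expect_gte(microhomology_len(rec, g), 8L)
  call <- junction_call(rec, g)
  expect_equal(call$mechanism, "NHEJ_altEJ_MMBIR")
})
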