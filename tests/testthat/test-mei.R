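# Retrotransposition annotation: tails, TSDs, orientation, transductions,
# decomposition and class assignment.

test_that("poly(A) tail scan applies length, purity and offset thresholds", {
  expect_null(scan_poly_tail(paste0(strrep("G", 20), strrep("A", 9)), "3p"))
  pt <- scan_poly_tail(paste0(strrep("G", 20), strrep("A", 12)), "3p")
  expect_equal(pt$length, 12L)
  expect_equal(pt$purity, 1)
  expect_equal(pt$offset_from_end, 0L)
  # 17-bp window with one interruption: purity 16/17 qualifies
  pt2 <- scan_poly_tail(paste0(strrep("C", 30), strrep("A", 8), "G",
                               strrep("A", 8)), "3p")
  expect_equal(pt2$length, 17L)
  expect_equal(pt2$purity, 16 / 17, tolerance = 1e-12)
  # a tail farther than max_offset from the end is not found
  expect_null(scan_poly_tail(paste0(strrep("A", 15), strrep("G", 60)), "3p"))
  # 5' poly(T)
  pt3 <- scan_poly_tail(paste0(strrep("T", 14), strrep("G", 30)), "5p")
  expect_equal(pt3$kind, "polyT")
  expect_equal(pt3$length, 14L)
})

test_that("poly tail scan equals the brute-force window oracle", {
  set.seed(31)
  for (i in 1:300) {
    s <- paste(sample(c("A", "A", "A", "C", "G", "T"), 80, replace = TRUE),
               collapse = "")
    got <- scan_poly_tail(s, "3p")
    want <- polytail_oracle(s)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$length, want$length)
      expect_equal(got$offset_from_end, want$offset)
    }
  }
})

test_that("TSD detection picks the longest exact terminal match", {
  set.seed(32)
  up <- paste0(rdna(99), "G")
  down <- paste0(substr(rdna(12), 1, 12), "C", rdna(87))
  # no terminal match against either flank (terminal bases forced apart:
  # the insert starts T / ends A, the flanks start G / end G)
  down_g <- paste0("G", rdna(99))
  up_g <- paste0(rdna(99), "G")
  expect_null(find_tsd(paste0("T", rdna(48), "A"), up_g, down_g))
  # insert prefix matching the downstream flank; extension blocked by
  # differing 13th bases ("A" in the insert vs "C" in the flank)
  ins5 <- paste0(substr(down, 1, 12), "A", rdna(60), "C")
  t5 <- find_tsd(ins5, up, down)
  expect_equal(t5$length, 12L)
  expect_equal(t5$end, "5p")
  # competing matches resolve toward the longer, then 3'
  ins_both <- paste0(substr(down, 1, 5), "A", rdna(39),
                     substr(up, 92, 100))
  substr(ins_both, 45L, 45L) <- "C"    # block 3' extension (up[91] = ?)
  if (substr(up, 91, 91) == "C") substr(ins_both, 45L, 45L) <- "T"
  if (substr(down, 6, 6) == "A") substr(ins_both, 6L, 6L) <- "T"
  tb <- find_tsd(ins_both, up, down)
  expect_equal(tb$length, 9L)
  expect_equal(tb$end, "3p")
  # agreement with the brute-force oracle on random cases
  for (i in 1:100) {
    u <- rdna(60); d <- rdna(60); s <- rdna(40)
    got <- find_tsd(s, u, d)
    want <- tsd_oracle(s, u, d)
    if (is.null(want)) expect_null(got) else {
      expect_equal(got$length, want$length)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("orientation and trimming recover the forward body exactly", {
  set.seed(33)
  db <- fixture_db()
  body <- db$seqs[["Alu"]]   # starts with G, ends A/T-free
  # flank position 11 ("C") differs from both the body start ("G") and a
  # poly(T) tail ("T"), so the planted 10-bp TSD is maximal in both
  # orientations; the upstream flank ends "C" so no competing 3' match
  down <- paste0(rdna(10), "C", rdna(89))
  up <- paste0(rdna(99), "C")
  tsd <- substr(down, 1, 10)
  fwd <- paste0(tsd, body, strrep("A", 20))
  ot <- orient_and_trim(fwd, find_tsd(fwd, up, down))
  expect_equal(ot$orientation, "+")
  expect_equal(ot$body, body)
  expect_equal(ot$tail$length, 20L)
  expect_equal(nchar(fwd), 10L + nchar(ot$body) + ot$trimmed_tail_bases)
  # minus-strand insert: leading TSD then reverse-complemented body+tail
  rev_ins <- paste0(tsd, revcomp(paste0(body, strrep("A", 20))))
  ot2 <- orient_and_trim(rev_ins, find_tsd(rev_ins, up, down))
  expect_equal(ot2$orientation, "-")
  expect_equal(ot2$body, body)
  expect_equal(ot2$tail$length, 20L)
})

test_that("3' transductions split the body and trace to their source", {
  set.seed(34)
  g <- fixture_genome()
  db <- fixture_db()
  seg <- genome_seq(g, "chrS", 200000, 200250)
  body <- paste0(db$seqs[["L1"]], strrep("A", 22), seg)
  td <- detect_transductions(body, g)
  expect_false(is.null(td$transduction))
  expect_equal(td$transduction$side, "3p")
  expect_equal(td$core, db$seqs[["L1"]])
  expect_gte(td$transduction$aligned_fraction, 0.8)
  src <- td$transduction$source
  expect_true(src$start < 200250 && src$end > 200000)
  # a single-tail body is a solo candidate
  solo <- detect_transductions(db$seqs[["L1"]], g)
  expect_null(solo$transduction)
  # a segment aligning below the threshold demotes the candidate
  part <- paste0(substr(seg, 1, 100), rdna(150))
  body2 <- paste0(db$seqs[["L1"]], strrep("A", 22), part)
  td2 <- detect_transductions(body2, g)
  expect_null(td2$transduction)
  expect_equal(td2$core, body2)
})

test_that("decomposition covers constructed inserts and rejects noise", {
  set.seed(35)
  db <- fixture_db()
  chain <- decompose_insert(db$seqs[["Alu"]], db)
  expect_equal(chain$coverage, 1)
  expect_equal(unique(chain$hits$target), "Alu")
  # twin-priming signature: minus-strand 5' piece plus forward remainder
  l1 <- db$seqs[["L1"]]
  twin <- paste0(revcomp(substr(l1, 1, 900)), substr(l1, 901, nchar(l1)))
  ch2 <- decompose_insert(twin, db)
  expect_gte(ch2$coverage, 0.99)
  expect_equal(ch2$hits$strand, c("-", "+"))
  # random sequence stays uncovered
  for (i in 1:20) {
    chr <- decompose_insert(rdna(1000), db)
    expect_lt(chr$coverage, 0.75)
  }
})

test_that("classification applies the 75% precedence rules", {
  set.seed(36)
  db <- fixture_db()
  g <- fixture_genome()
  tail <- scan_poly_tail(paste0(strrep("C", 20), strrep("A", 25)), "3p")
  # solo element, canonical
  chain <- decompose_insert(db$seqs[["Alu"]], db)
  ann <- classify_insert(chain, db, tail = tail, core = db$seqs[["Alu"]])
  expect_equal(ann$class, "solo_Alu")
  expect_true(ann$canonical)
  expect_true(ann$full_length)
  # same chain without a tail is a non-canonical MEI flagged no_polyA
  ann2 <- classify_insert(chain, db, tail = NULL, core = db$seqs[["Alu"]])
  expect_equal(ann2$class, "non_canonical_MEI")
  expect_true("no_polyA" %in% ann2$flags)
  # processed pseudogene: exon-copied core
  exons <- data.frame(chrom = "chrS", start = c(250000L, 260000L),
                      end = c(250300L, 260200L), id = c("e1", "e2"))
  core <- paste0(genome_seq(g, "chrS", 250000, 250300),
                 genome_seq(g, "chrS", 260000, 260200))
  ch3 <- decompose_insert(core, db, g)
  ann3 <- classify_insert(ch3, db, tail = tail, exons = exons, core = core)
  expect_equal(ann3$class, "processed_pseudogene")
  expect_equal(ann3$exon_count, 2L)
  # the same genomic core outside exons is an orphan transduction
  ann4 <- classify_insert(ch3, db, tail = tail, core = core)
  expect_equal(ann4$class, "orphan_td")
  expect_equal(ann4$transduction$side, "orphan")
})

test_that("L1 subfamily diagnostics follow the rule table", {
  db <- fixture_db()   # built with ACA + T/G: Ta-1
  l1 <- db$seqs[["L1"]]
  set_bases <- function(seq, at, what) {
    ch <- strsplit(seq, "")[[1]]
    ch[at] <- what
    paste(ch, collapse = "")
  }
  cases <- list(
    list(core = set_bases(l1, 5929:5931, c("A", "C", "G")), want = "pre-Ta"),
    list(core = l1, want = "Ta-1"),
    list(core = set_bases(l1, c(5535, 5538), c("G", "C")), want = "Ta-0"),
    list(core = set_bases(l1, 5535, "A"), want = "Ta"),
    list(core = set_bases(l1, 5929:5931, c("G", "C", "G")),
         want = "undetermined"),
    list(core = substr(l1, 1, 5000), want = "undetermined")
  )
  for (cs in cases) {
    chain <- decompose_insert(cs$core, db)
    expect_equal(l1_subfamily(chain, cs$core, db), cs$want)
  }
})

test_that("ERV and NUMT classification follow their coverage rules", {
  set.seed(37)
  db <- fixture_db()
  ltr <- db$seqs[["LTR5"]]
  expect_equal(classify_erv(ltr, db)$class, "solo_LTR")
  full <- paste0(ltr, db$seqs[["ERVK_int"]], ltr)
  erv <- classify_erv(full, db)
  expect_equal(erv$class, "ERVK")
  expect_equal(erv$n_ltr, 2L)
  # 60% LTR / 40% random does not reach the coverage rule
  diluted <- paste0(ltr, rdna(270))
  expect_null(classify_erv(diluted, db))
  mito <- db$seqs[["MT"]]
  expect_gte(classify_numt(substr(mito, 1000, 1500), mito)$coverage, 0.99)
  # an insert spanning the circular origin reports two wrapped fragments
  wrap <- paste0(substr(mito, 2800, 3000), substr(mito, 1, 200))
  numt <- classify_numt(wrap, mito)
  expect_false(is.null(numt))
  expect_equal(nrow(numt$fragments), 2L)
  expect_null(classify_numt(paste0(substr(mito, 1, 250), rdna(250)), mito))
})

test_that("annotation is invariant under reverse complementation", {
  set.seed(38)
  g <- fixture_genome()
  db <- fixture_db()
  # pick a site where the base after the 14-bp TSD window blocks extension
  # against both the element start (G) and a leading poly(T) (T)
  pos <- 150000L
  while (!substr(g[["chrS"]], pos + 15L, pos + 15L) %in% c("A", "C")) {
    pos <- pos + 101L
  }
  down <- genome_seq(g, "chrS", pos, pos + 100)
  tsd <- substr(down, 1, 14)
  unit <- paste0(db$seqs[["Alu"]], strrep("A", 24))
  fwd <- paste0(tsd, unit)
  rev_ <- paste0(tsd, revcomp(unit))
  up <- genome_seq(g, "chrS", pos - 100, pos)
  a1 <- annotate_insert(fwd, up, down, g, db)
  a2 <- annotate_insert(rev_, up, down, g, db)
  expect_equal(a1$class, "solo_Alu")
  expect_equal(a2$class, "solo_Alu")
  expect_equal(a1$orientation, "+")
  expect_equal(a2$orientation, "-")
  expect_equal(a1$tsd$length, a2$tsd$length)
  expect_equal(a1$tail$length, a2$tail$length)
})

test_that("allele length is conserved across trimmed components", {
  set.seed(39)
  g <- fixture_genome()
  db <- fixture_db()
  pos <- 170000L
  # the base after the TSD window must differ from the element start (G)
  while (substr(g[["chrS"]], pos + 12L, pos + 12L) == "G") pos <- pos + 101L
  down <- genome_seq(g, "chrS", pos, pos + 100)
  tsd <- substr(down, 1, 11)
  insert <- paste0(tsd, db$seqs[["SVA_alu_like"]], db$seqs[["SVA_vntr"]],
                   db$seqs[["SVA_sine_r"]], strrep("A", 30))
  ann <- annotate_insert(insert, genome_seq(g, "chrS", pos - 100, pos),
                         down, g, db)
  expect_equal(ann$class, "solo_SVA")
  expect_equal(nchar(insert),
               ann$tsd$length + ann$tail$length + ann$chain$query_len)
})
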