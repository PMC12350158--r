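# Masking, non-overlapping partitioning, pseudo-haplotype implantation,
# record merging and novel-bubble accounting.

test_that("masking replaces bases with N and preserves length", {
  g <- c(chrA = strrep("ACGT", 2500))
  masked <- mask_regions(g, data.frame(chrom = "chrA", start = 1000L,
                                       end = 2000L))
  expect_equal(nchar(masked[["chrA"]]), 10000L)
  expect_equal(substr(masked[["chrA"]], 1001, 2000), strrep("N", 1000))
  expect_equal(substr(masked[["chrA"]], 1, 1000), substr(g[["chrA"]], 1, 1000))
  # empty mask is the identity
  expect_identical(mask_regions(g, data.frame(chrom = character(0),
                                              start = integer(0),
                                              end = integer(0))), g)
  expect_error(mask_regions(g, data.frame(chrom = "chrA", start = 9000L,
                                          end = 11000L)), "out of bounds")
  # records intersecting the mask are dropped
  recs <- sv_records(id = c("in", "out"), chrom = "chrA",
                     start = c(1500L, 5000L), ref = c("A", "C"),
                     alt = c(paste0("A", strrep("G", 60)),
                             paste0("C", strrep("T", 60))))
  fl <- filter_masked_records(recs, data.frame(chrom = "chrA", start = 1000L,
                                               end = 2000L))
  expect_equal(fl$kept$id, "out")
  expect_equal(fl$dropped$id, "in")
})

test_that("partitioning yields max-depth many internally disjoint groups", {
  # three pairwise-overlapping deletions need three groups
  g <- fixture_genome()
  mkdel <- function(id, start, len) {
    one_record(id, "chrS", start, genome_seq(g, "chrS", start, start + len),
               genome_seq(g, "chrS", start, start + 1))
  }
  recs <- rbind(mkdel("a", 1000L, 500L), mkdel("b", 1200L, 500L),
                mkdel("c", 1400L, 500L))
  parts <- partition_nonoverlapping(recs)
  expect_equal(max(parts$group_id), 3L)
  # fully disjoint callset fits one group
  recs2 <- rbind(mkdel("a", 1000L, 200L), mkdel("b", 2000L, 200L),
                 mkdel("c", 3000L, 200L))
  expect_equal(max(partition_nonoverlapping(recs2)$group_id), 1L)
  # two insertions at the same position land in different groups
  anchor <- genome_seq(g, "chrS", 5000, 5001)
  ins <- rbind(
    one_record("i1", "chrS", 5000L, anchor, paste0(anchor, strrep("A", 60))),
    one_record("i2", "chrS", 5000L, anchor, paste0(anchor, strrep("C", 60)))
  )
  expect_equal(max(partition_nonoverlapping(ins)$group_id), 2L)
})

test_that("implantation conserves lengths, round trips and guards REF", {
  set.seed(71)
  g <- c(chrS = rdna(20000))
  anchor1 <- substr(g[[1]], 1001, 1001)
  del_ref <- substr(g[[1]], 5001, 5101)
  grp <- rbind(
    one_record("ins", "chrS", 1000L, anchor1,
               paste0(anchor1, rdna(100))),
    one_record("del", "chrS", 5000L, del_ref, substr(del_ref, 1, 1))
  )
  ph <- implant_pseudohaplotype(g, grp, 3L)
  expect_equal(names(ph$sequences), "chrS_group3")
  expect_equal(nchar(ph$sequences[[1]]), 20000L + 100L - 100L)
  # re-extract each implanted allele through the coordinate map
  for (i in seq_len(nrow(grp))) {
    pp <- pseudohap_pos(ph, "chrS", grp$start[i])
    got <- substr(ph$sequences[[1]], pp + 1L, pp + nchar(grp$alt[i]))
    expect_identical(got, grp$alt[i])
  }
  # stale coordinates are an error
  bad <- grp
  wrong <- setdiff(c("A", "C", "G", "T"), substr(bad$ref[2], 1, 1))[1]
  bad$ref[2] <- paste0(wrong, substr(bad$ref[2], 2, nchar(bad$ref[2])))
  expect_error(implant_pseudohaplotype(g, bad), "REF mismatch")
})

test_that("merging contig records adds the intervening reference to both
           alleles and re-alignment recovers the member gaps", {
  set.seed(72)
  g <- fixture_genome()
  mkdel <- function(id, start, len) {
    one_record(id, "chrS", start, genome_seq(g, "chrS", start, start + len),
               genome_seq(g, "chrS", start, start + 1))
  }
  a <- mkdel("a", 10000L, 61L)
  b <- mkdel("b", 10360L, 61L)
  merged <- merge_contig_records(rbind(a, b), g)
  expect_equal(merged$svtype, "COMPLEX")
  expect_equal(merged$start, 10000L)
  expect_equal(merged$end, 10421L)
  expect_equal(nchar(merged$ref) - nchar(merged$alt), 120L)
  # single record passes through unchanged
  expect_identical(merge_contig_records(a, g)$alt, a$alt)
  # re-aligning merged ALT to merged REF recovers two 60-bp deletion gaps
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(merged$alt), Biostrings::DNAString(merged$ref),
    type = "global", gapOpening = 10, gapExtension = 0.5
  )
  gaps <- gregexpr("-+", as.character(Biostrings::alignedPattern(aln)))[[1]]
  expect_equal(length(gaps), 2L)
  expect_equal(sort(attr(gaps, "match.length")), c(60L, 60L))
  expect_error(merge_contig_records(rbind(a, {
    x <- b; x$chrom <- "chrZ"; x
  }), g), "different chromosomes")
})

test_that("novel bubbles are those at least 1 kb from any original bubble", {
  aug <- data.frame(chrom = "chr1", start = c(1000L, 5000L, 9000L),
                    end = c(1100L, 5100L, 9100L))
  orig <- data.frame(chrom = "chr1", start = c(1500L, 7600L),
                     end = c(1600L, 7700L))
  res <- novel_bubble_filter(aug, orig)
  expect_equal(res$novel, c(FALSE, TRUE, TRUE))  # 400 bp, 2.4 kb, 1.3 kb
  # empty original set: everything is novel
  res2 <- novel_bubble_filter(aug, orig[0, ])
  expect_true(all(res2$novel))
  # agreement with brute-force nearest distance on random sets
  set.seed(73)
  for (i in 1:20) {
    a <- sort(sample.int(1e6, 15))
    b <- sort(sample.int(1e6, 10))
    aug_r <- data.frame(chrom = "chr1", start = a, end = a + 50L)
    orig_r <- data.frame(chrom = "chr1", start = b, end = b + 50L)
    res_r <- novel_bubble_filter(aug_r, orig_r)
    brute <- vapply(seq_along(a), function(k) {
      gaps <- pmax(0L, pmax(b - (a[k] + 50L), a[k] - (b + 50L)))
      min(gaps)
    }, numeric(1))
    expect_equal(res_r$novel, brute >= 1000)
  }
})
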