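# Recurrence screen: shortlisting, recurrence-indicating SNPs, haplotype
# clustering and the supported/unsupported verdict.

test_that("shortlisting applies every filter and names missing fields", {
  dels <- data.frame(
    id = c("ok", "long", "hom_low", "hom_high", "af", "unphased", "na_hom"),
    svlen = c(800L, 6000L, 800L, 800L, 800L, 800L, 800L),
    hom_len = c(295L, 295L, 150L, 9500L, 295L, 295L, NA),
    af = c(0.5, 0.5, 0.5, 0.5, 0.35, 0.5, 0.5),
    phased = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  res <- shortlist_candidates(dels)
  expect_equal(res$kept$id, "ok")
  reasons <- setNames(res$excluded$reason, res$excluded$id)
  expect_equal(unname(reasons["long"]), "length")
  expect_equal(unname(reasons["hom_low"]), "homology")
  expect_equal(unname(reasons["hom_high"]), "homology")
  expect_equal(unname(reasons["af"]), "allele_frequency")
  expect_equal(unname(reasons["unphased"]), "unphased")
  expect_match(reasons["na_hom"], "missing:hom_len")
  # Hardy-Weinberg / Mendelian screens exclude when provided
  dels2 <- data.frame(id = c("a", "b"), svlen = 800L, hom_len = 295L,
                      af = 0.5, phased = TRUE, hwe_ok = c(TRUE, FALSE))
  expect_equal(shortlist_candidates(dels2)$kept$id, "a")
})

test_that("recurrence SNPs require all four allele-deletion combinations", {
  # 8 haplotypes, deletion on the last four
  del <- c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L)
  snp_tag <- c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L)   # perfect tagging: 2 combos
  snp_rec <- c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L)   # all four combinations
  snp_rare <- c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L)  # below the MAF threshold
  panel <- hap_panel(c(1000L, 15000L, 18000L),
                     cbind(snp_tag, snp_rec, snp_rare), del,
                     del_start = 9500L, del_end = 10500L)
  snps <- recurrence_snps(panel)
  expect_equal(snps$position, 15000L)
  expect_equal(snps$side, "downstream")
  # dropping the MAF filter does not rescue the tagging or the rare SNP:
  # neither shows all four combinations
  expect_equal(recurrence_snps(panel, min_maf = 0)$position, 15000L)
})

test_that("qualifying SNPs match the exhaustive 2x2 occupancy oracle", {
  set.seed(81)
  for (i in 1:30) {
    n <- sample(10:50, 1); m <- sample(20:200, 1)
    mat <- matrix(rbinom(n * m, 1, runif(1, 0.2, 0.8)), n, m)
    del <- rbinom(n, 1, 0.5)
    pos <- sort(sample.int(20000, m))
    panel <- hap_panel(pos, mat, del, del_start = 9900L, del_end = 10100L)
    got <- recurrence_snps(panel, window = 20000, min_maf = 0.10)
    oracle <- vapply(seq_len(m), function(j) {
      a <- mat[, j]
      maf <- min(mean(a), 1 - mean(a))
      in_win <- pos[j] >= 10000 - 10000 & pos[j] <= 10000 + 10000
      outside <- pos[j] < 9900 || pos[j] >= 10100
      maf >= 0.10 && in_win && outside &&
        length(unique(paste(a, del))) == 4
    }, logical(1))
    expect_equal(got$position, pos[oracle])
  }
})

test_that("haplotype clustering separates divergent blocks and tolerates
           degenerate panels", {
  set.seed(82)
  core1 <- rbinom(60, 1, 0.5); core2 <- rbinom(60, 1, 0.5)
  mat <- rbind(matrix(rep(core1, 10), 10, byrow = TRUE),
               matrix(rep(core2, 10), 10, byrow = TRUE))
  panel <- hap_panel(seq(1000, by = 1500, length.out = 60), mat,
                     rep(c(0L, 1L), each = 10), 45000L, 45800L)
  cl <- cluster_haplotypes(panel)
  expect_equal(length(unique(cl$groups)), 2L)
  expect_equal(length(unique(cl$groups[1:10])), 1L)
  # single haplotype and constant matrix degenerate to one group
  p1 <- hap_panel(c(100L, 200L), matrix(c(0L, 1L), 1), 1L, 120L, 150L)
  expect_equal(cluster_haplotypes(p1)$groups, 1L)
  pc <- hap_panel(c(100L, 200L), matrix(0L, 5, 2), rep(0L, 5), 120L, 150L)
  expect_equal(unique(cluster_haplotypes(pc)$groups), 1L)
})

test_that("clustering is invariant to SNP column order", {
  set.seed(83)
  sim <- simulate_recurrence_panel(n_haplotypes = 40, n_snps = 80,
                                   n_origins = 2, seed = 83)
  p <- sim$panel
  perm <- sample(ncol(p$matrix))
  p2 <- hap_panel(p$snp_positions[perm], p$matrix[, perm], p$del_state,
                  p$del_start, p$del_end)
  c1 <- cluster_haplotypes(p)
  c2 <- cluster_haplotypes(p2)
  expect_equal(adjusted_rand(c1$groups, c2$groups), 1)
})

test_that("clustering recovers planted groups under 1% noise", {
  set.seed(84)
  ari <- vapply(1:25, function(r) {
    cores <- matrix(rbinom(4 * 120, 1, 0.5), 4)
    origin <- rep(1:4, each = 12)
    mat <- cores[origin, ]
    flip <- matrix(rbinom(length(mat), 1, 0.01), nrow(mat))
    mat <- abs(mat - flip)
    panel <- hap_panel(seq(500, by = 800, length.out = 120), mat,
                       rbinom(48, 1, 0.5), 47000L, 48000L)
    adjusted_rand(cluster_haplotypes(panel)$groups, origin)
  }, numeric(1))
  expect_gte(mean(ari >= 0.9), 0.9)
})

test_that("verdicts: dual-origin supported, single-origin unsupported", {
  s1 <- simulate_recurrence_panel(n_origins = 1, seed = 85)
  r1 <- assess_recurrence(s1$panel)
  expect_equal(r1$verdict, "unsupported")
  s2 <- simulate_recurrence_panel(n_origins = 2, seed = 86)
  r2 <- assess_recurrence(s2$panel)
  expect_equal(r2$verdict, "supported")
  expect_true(all(c("upstream", "downstream") %in% r2$recurrence_snps$side))
  # inspection table covers every group and reports deletion frequencies
  expect_equal(sum(r2$cluster_table$n_haplotypes), 200L)
  expect_true(all(r2$cluster_table$del_frequency >= 0 &
                    r2$cluster_table$del_frequency <= 1))
})

test_that("without mutations or recombination a single origin yields no
           recurrence-indicating SNP at all", {
  sim <- simulate_recurrence_panel(n_origins = 1, mut_rate = 0,
                                   recomb_rate = 0, seed = 87)
  expect_equal(nrow(recurrence_snps(sim$panel)), 0L)
})
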