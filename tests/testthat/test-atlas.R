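# Transduction source clustering, progenitor assignment and bias testing.

td_df <- function(starts, sides = "3p", chrom = "chr1", len = 300L) {
  data.frame(sv_id = paste0("t", seq_along(starts)), side = sides,
             chrom = chrom, start = starts, end = starts + len,
             stringsAsFactors = FALSE)
}

test_that("source clustering merges padded intervals transitively", {
  # 15 kb apart: padded intervals touch -> one cluster
  cl <- cluster_sources(td_df(c(100000L, 115000L)))
  expect_equal(nrow(cl$regions), 1L)
  # 25 kb apart -> two clusters
  cl2 <- cluster_sources(td_df(c(100000L, 125000L)))
  expect_equal(nrow(cl2$regions), 2L)
  # chain at 18-kb steps merges transitively into one cluster
  starts <- seq(100000L, by = 18000L, length.out = 6)
  cl3 <- cluster_sources(td_df(starts))
  expect_equal(nrow(cl3$regions), 1L)
  expect_equal(cl3$assignment, rep(1L, 6))
})

test_that("clustering is order invariant and conserves counts", {
  set.seed(61)
  starts <- sample.int(2e6, 40)
  tds <- td_df(starts, sides = sample(c("5p", "3p", "orphan"), 40,
                                      replace = TRUE))
  cl <- cluster_sources(tds)
  perm <- sample(nrow(tds))
  cl2 <- cluster_sources(tds[perm, ])
  # same partition under permutation
  key1 <- split(tds$sv_id, cl$assignment)
  key2 <- split(tds$sv_id[perm], cl2$assignment)
  norm <- function(k) sort(vapply(k, function(x)
    paste(sort(x), collapse = ","), ""))
  expect_equal(norm(key1), norm(key2))
  atlas <- build_source_atlas(tds)
  expect_equal(sum(atlas$n_5p + atlas$n_3p + atlas$n_orphan), nrow(tds))
})

test_that("progenitor assignment enforces full-length thresholds", {
  region <- data.frame(region_id = 1L, chrom = "chr1", start = 90000L,
                       end = 130000L)
  db <- data.frame(
    chrom = "chr1", start = c(100000L, 110000L),
    end = c(106000L, 115000L), class = c("L1", "L1"),
    subfamily = c("Ta-1", "Ta-0"), orientation = c("+", "-"),
    in_reference = TRUE, stringsAsFactors = FALSE
  )
  # 6.0-kb L1 qualifies; a 5.0-kb truncated copy does not
  hit <- assign_progenitor(region, db)
  expect_equal(hit$start, 100000L)
  db2 <- db[1, ]; db2$end <- db2$start + 5000L
  expect_null(assign_progenitor(region, db2))
  # SVA threshold is 1 kb
  db3 <- data.frame(chrom = "chr1", start = 100000L, end = 101100L,
                    class = "SVA", subfamily = "SVA_E", orientation = "+",
                    in_reference = TRUE)
  expect_equal(assign_progenitor(region, db3)$class, "SVA")
  # two qualifying candidates: nearest to the centroid wins
  db4 <- db
  db4$end <- db4$start + 6000L
  near <- assign_progenitor(region, db4, centroid = 112000)
  expect_equal(near$start, 110000L)
})

test_that("binomial bias p-values match closed forms and BH matches the
           step-up oracle", {
  loci <- data.frame(n_5p = c(5L, 10L, 0L, 2L), n_3p = c(0L, 0L, 10L, 2L))
  res <- bias_test(loci)
  expect_equal(res$p_value[1], 2 * 0.5^5, tolerance = 1e-12)
  expect_equal(res$p_value[2], 2 * 0.5^10, tolerance = 1e-12)
  expect_equal(res$p_value[3], 2 * 0.5^10, tolerance = 1e-12)
  expect_equal(res$bias[1], "none")   # p = 0.0625: no call at 0.05
  expect_equal(res$bias[4], "untested")
  set.seed(62)
  p <- runif(20)
  expect_equal(stats::p.adjust(p, "BH"), bh_step_up(p), tolerance = 1e-12)
  # BH monotonicity on the atlas output
  loci2 <- data.frame(n_5p = rbinom(15, 40, 0.5), n_3p = rbinom(15, 40, 0.5))
  loci2 <- loci2[loci2$n_5p + loci2$n_3p >= 5, ]
  r2 <- bias_test(loci2)
  o <- order(r2$p_value)
  expect_false(is.unsorted(r2$p_adjusted[o]))
  expect_equal(r2$p_adjusted, bh_step_up(r2$p_value), tolerance = 1e-12)
})

test_that("loci below five non-orphan transductions are untested", {
  loci <- data.frame(n_5p = c(2L, 3L), n_3p = c(2L, 2L))
  res <- bias_test(loci)
  expect_equal(res$bias, c("untested", "tested" = "none")[c(1, 2)],
               ignore_attr = TRUE)
  expect_true(is.na(res$p_value[1]))
  expect_false(is.na(res$p_value[2]))
})
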