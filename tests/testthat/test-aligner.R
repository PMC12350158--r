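# Local similarity search and optimal chaining.

test_that("exact substring queries produce full-length hits on both strands", {
  set.seed(21)
  target <- c(t1 = rdna(2000))
  q <- substr(target[[1]], 501, 800)
  h <- local_hits(q, target, seed_word = 11)
  expect_equal(nrow(h), 1L)
  expect_equal(h$query_start, 0L)
  expect_equal(h$query_end, 300L)
  expect_equal(h$target_start, 500L)
  expect_equal(h$identity, 1)
  expect_equal(h$strand, "+")
  hr <- local_hits(revcomp(q), target, seed_word = 11)
  expect_equal(hr$strand, "-")
  expect_equal(hr$target_start, 500L)
  expect_equal(hr$target_end, 800L)
})

test_that("queries sharing no seed word yield no hits; short queries warn", {
  target <- c(t1 = strrep("A", 500))
  expect_equal(nrow(local_hits(strrep("C", 100), target, seed_word = 8)), 0L)
  expect_warning(h <- local_hits("ACG", target, seed_word = 8), "seed")
  expect_equal(nrow(h), 0L)
})

test_that("hit discovery is strand symmetric on mutated copies", {
  set.seed(22)
  for (rep in 1:5) {
    target <- c(t1 = rdna(1500))
    q0 <- substr(target[[1]], 301, 700)
    ch <- strsplit(q0, "")[[1]]
    at <- sample(400, 30)
    ch[at] <- vapply(ch[at], function(b) sample(setdiff(c("A", "C", "G", "T"),
                                                        b), 1), "")
    q <- paste(ch, collapse = "")
    hf <- local_hits(q, target, seed_word = 9)
    hr <- local_hits(revcomp(q), target, seed_word = 9)
    expect_equal(nrow(hf), nrow(hr))
    expect_equal(sort(hf$target_start), sort(hr$target_start))
    expect_equal(sort(hf$length), sort(hr$length))
  }
})

test_that("uniqueness reflects the score gap to alternative placements", {
  set.seed(23)
  block <- rdna(200)
  target <- c(t1 = paste0(rdna(300), block, rdna(300), block, rdna(300)))
  h <- local_hits(block, target, seed_word = 11, min_uniqueness = 0)
  two <- h[h$length == 200, ]
  expect_equal(nrow(two), 2L)
  expect_true(all(two$uniqueness <= 0))   # equal-scoring twin placements
  filtered <- local_hits(block, target, seed_word = 11, min_uniqueness = 10)
  expect_false(any(filtered$length == 200))
})

test_that("chain_best solves weighted interval scheduling exactly", {
  hits <- data.frame(
    query_start = c(0L, 100L), query_end = c(100L, 200L), target = "t",
    target_start = c(0L, 100L), target_end = c(100L, 200L), strand = "+",
    length = 100L, matches = 100L, identity = 1, score = 100,
    uniqueness = Inf
  )
  ch <- chain_best(hits, 200L)
  expect_equal(ch$coverage, 1)
  expect_equal(nrow(ch$hits), 2L)
  expect_equal(chain_best(hits[0, ], 200L)$coverage, 0)
  one <- chain_best(hits[1, ], 100L)
  expect_equal(one$coverage, 1)
})

test_that("chain_best equals exhaustive search on random instances", {
  set.seed(24)
  for (i in 1:150) {
    k <- sample.int(8, 1)
    qs <- sample(0:150, k, replace = TRUE)
    len <- sample(5:60, k, replace = TRUE)
    hits <- data.frame(query_start = qs, query_end = qs + len, target = "t",
                       target_start = qs, target_end = qs + len,
                       strand = "+", length = len, matches = len,
                       identity = 1, score = sample(5:100, k, replace = TRUE),
                       uniqueness = Inf)
    a <- chain_best(hits, 220L)
    b <- chain_best_exhaustive(hits, 220L)
    expect_equal(a$covered_bases, b$covered_bases)
    expect_equal(nrow(a$hits), nrow(b$hits))
    expect_equal(sum(a$hits$score), sum(b$hits$score))
  }
})

test_that("adding a hit never reduces the optimal chain coverage", {
  set.seed(25)
  for (i in 1:50) {
    k <- sample(2:9, 1)
    qs <- sample(0:150, k, replace = TRUE)
    len <- sample(5:60, k, replace = TRUE)
    hits <- data.frame(query_start = qs, query_end = qs + len, target = "t",
                       target_start = qs, target_end = qs + len,
                       strand = "+", length = len, matches = len,
                       identity = 1, score = len, uniqueness = Inf)
    full <- chain_best(hits, 220L)$covered_bases
    drop1 <- chain_best(hits[-1, ], 220L)$covered_bases
    expect_gte(full, drop1)
  }
})

test_that("seed indexing is transparent to the results", {
  set.seed(26)
  target <- c(t1 = rdna(3000))
  q <- substr(target[[1]], 1001, 1400)
  plain <- local_hits(q, target, seed_word = 11)
  indexed <- local_hits(q, index_targets(target, 11), seed_word = 11)
  expect_identical(plain, indexed)
})
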