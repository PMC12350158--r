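# Shared fixtures and independent reference implementations (oracles).

fixture_db <- local({
  db <- NULL
  function() {
    if (is.null(db)) db <<- synthetic_consensus_db(7)
    db
  }
})

fixture_genome <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- simulate_genome(4e5, seed = 7)
    g
  }
})

# random DNA string helper for tests
rdna <- function(n, gc = 0.45) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Benjamini-Hochberg step-up, written independently of stats::p.adjust
bh_step_up <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# brute-force longest qualifying poly-base window near the 3' end
polytail_oracle <- function(seq, base = "A", min_len = 10, min_purity = 0.90,
                            max_offset = 50) {
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  best <- NULL
  for (j in seq_len(n)) {
    if (n - j > max_offset || ch[j] != base) next
    for (i in seq_len(j)) {
      if (ch[i] != base) next
      len <- j - i + 1
      if (len < min_len) next
      pur <- sum(ch[i:j] == base) / len
      if (pur < min_purity) next
      if (is.null(best) || len > best$length ||
          (len == best$length && (n - j) < best$offset)) {
        best <- list(length = len, offset = n - j)
      }
    }
  }
  best
}

# brute-force longest exact terminal TSD match (both pairings)
tsd_oracle <- function(alt_seq, ref_up, ref_down, max_len = 50) {
  n <- nchar(alt_seq)
  k5 <- 0
  while (k5 < min(n, max_len) &&
         substr(alt_seq, k5 + 1, k5 + 1) ==
         substr(ref_down, k5 + 1, k5 + 1)) k5 <- k5 + 1
  k3 <- 0
  nu <- nchar(ref_up)
  while (k3 < min(n, max_len) &&
         substr(alt_seq, n - k3, n - k3) ==
         substr(ref_up, nu - k3, nu - k3)) k3 <- k3 + 1
  if (k5 == 0 && k3 == 0) return(NULL)
  if (k3 >= k5) list(length = k3, end = "3p") else list(length = k5, end = "5p")
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# one-row record constructor for junction tests
one_record <- function(id, chrom, start, ref, alt) {
  sv_records(id = id, chrom = chrom, start = start, ref = ref, alt = alt)[1, ]
}
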