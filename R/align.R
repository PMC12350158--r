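# Seed-and-extend local similarity search and optimal chaining. Hits are
# gapless diagonal alignments: seeds (exact k-mer matches) are grouped by
# diagonal, merged into runs and extended with an X-drop criterion. Indels in
# an allele therefore surface as separate chain segments rather than as gaps
# inside one hit, which is what the downstream decomposition logic expects.

# Integer codes of all k-mers of an integer-coded sequence (A/C/G/T ->
# 0..3); windows containing any other letter code to NA. Exact for k <= 16
# (codes held in doubles).
kmer_codes <- function(vi, k) {
  n <- length(vi)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  codes <- numeric(m)
  for (j in seq_len(k)) {
    codes <- codes * 4 + vi[j:(j + m - 1L)]
  }
  codes
}

BASE_CODE <- {
  bc <- rep(NA_integer_, 128)
  bc[utf8ToInt("A")] <- 0L; bc[utf8ToInt("C")] <- 1L
  bc[utf8ToInt("G")] <- 2L; bc[utf8ToInt("T")] <- 3L
  bc
}

seq_base_codes <- function(seq) BASE_CODE[utf8ToInt(seq)]

# Precomputed seed index of one target sequence for a given seed length.
build_seed_index <- function(target, k) {
  ti <- utf8ToInt(target)
  codes <- kmer_codes(BASE_CODE[ti], k)
  ok <- which(!is.na(codes))
  o <- ok[order(codes[ok])]
  list(k = k, ti = ti, codes_sorted = codes[o], pos_sorted = o - 1L)
}

#' Attach precomputed seed indexes to a target collection
#'
#' Building the k-mer seed index of a large target (e.g. a whole genome)
#' once and reusing it across many [local_hits()] calls avoids re-indexing
#' per query.
#'
#' @param targets Named character vector of target sequences.
#' @param seed_word Seed length(s) to index.
#' @return The targets with an index attribute consulted by [local_hits()].
#' @export
index_targets <- function(targets, seed_word) {
  idx <- attr(targets, "sv_seed_index")
  if (is.null(idx)) idx <- list()
  for (k in seed_word) {
    key <- as.character(k)
    if (is.null(idx[[key]])) idx[[key]] <- list()
    for (tn in names(targets)) {
      idx[[key]][[tn]] <- build_seed_index(targets[[tn]], k)
    }
  }
  attr(targets, "sv_seed_index") <- idx
  targets
}

# Locate exact seed matches of every query k-mer in one indexed target.
# Returns a data.frame(qpos, tpos) of 0-based offsets.
seed_matches <- function(query, index) {
  k <- index$k
  nq <- nchar(query)
  if (nq < k || length(index$codes_sorted) == 0) {
    return(data.frame(qpos = integer(0), tpos = integer(0)))
  }
  qc <- kmer_codes(seq_base_codes(query), k)
  qok <- which(!is.na(qc))
  if (length(qok) == 0) {
    return(data.frame(qpos = integer(0), tpos = integer(0)))
  }
  cs <- index$codes_sorted
  hi <- findInterval(qc[qok], cs)
  lo <- findInterval(qc[qok] - 0.5, cs)
  cnt <- hi - lo
  keep <- cnt > 0
  if (!any(keep)) {
    return(data.frame(qpos = integer(0), tpos = integer(0)))
  }
  lo <- lo[keep]; cnt <- cnt[keep]
  qpos <- rep(qok[keep] - 1L, cnt)
  tpos <- index$pos_sorted[sequence(cnt) + rep(lo, cnt)]
  data.frame(qpos = qpos, tpos = tpos)
}

# Gapless X-drop extension of a diagonal seed run. qi/ti are utf8ToInt
# vectors of the full query/target; a,b are 1-based query bounds of the run;
# d is the diagonal offset (tpos - qpos). Returns 1-based [A,B] query span.
xdrop_extend <- function(qi, ti, a, b, d, xdrop = 40, match = 1L, mismatch = 2L) {
  nq <- length(qi); nt <- length(ti)
  lo <- max(1L, 1L - d)
  hi <- min(nq, nt - d)
  # chunked X-drop: identical result to scanning the whole diagonal, but a
  # random (non-homologous) diagonal terminates within the first chunk
  extend_dir <- function(from, limit, step) {
    offset <- 0L; best_off <- 0L
    best_sc <- 0; last_sc <- 0; run_max <- 0
    chunk <- 512L
    while (TRUE) {
      remaining <- (limit - from) * step - offset
      if (remaining <= 0L) break
      take <- min(chunk, remaining)
      idx <- from + step * (offset + seq_len(take))
      sc <- last_sc + cumsum(ifelse(qi[idx] == ti[idx + d], match, -mismatch))
      rm_ <- cummax(pmax(run_max, sc))
      stop_at <- which(rm_ - sc >= xdrop)
      lim <- if (length(stop_at)) stop_at[1] else take
      wm <- which.max(sc[seq_len(lim)])
      if (sc[wm] > best_sc) { best_sc <- sc[wm]; best_off <- offset + wm }
      if (length(stop_at)) break
      last_sc <- sc[take]
      run_max <- rm_[take]
      offset <- offset + take
    }
    best_off
  }
  B <- b + extend_dir(b, hi, 1L)
  A <- a - extend_dir(a, lo, -1L)
  # trim ends to matching bases
  while (A <= B && qi[A] != ti[A + d]) A <- A + 1L
  while (B >= A && qi[B] != ti[B + d]) B <- B - 1L
  c(A, B)
}

empty_hits <- function() {
  data.frame(
    query_start = integer(0), query_end = integer(0), target = character(0),
    target_start = integer(0), target_end = integer(0), strand = character(0),
    length = integer(0), matches = integer(0), identity = numeric(0),
    score = numeric(0), uniqueness = numeric(0), stringsAsFactors = FALSE
  )
}

# One-strand hit discovery against a single indexed target.
hits_one_strand <- function(query, index, tname, k, min_identity,
                            max_seed_gap, xdrop, min_hit_len) {
  sm <- seed_matches(query, index)
  if (nrow(sm) == 0) return(empty_hits())
  qi <- utf8ToInt(query); ti <- index$ti
  diag_all <- sm$tpos - sm$qpos
  qp_by_diag <- split(sm$qpos, diag_all)
  out <- matrix(0L, nrow = 32L, ncol = 4L)  # A, B, diag, nmatch
  n_out <- 0L
  for (dk in names(qp_by_diag)) {
    d <- as.integer(dk)
    qp <- sort(unique(qp_by_diag[[dk]]))
    # split seed positions into runs separated by > max_seed_gap
    brk <- which(diff(qp) > max_seed_gap)
    run_start <- c(1L, brk + 1L)
    run_end <- c(brk, length(qp))
    spans <- list()
    for (r in seq_along(run_start)) {
      a <- qp[run_start[r]] + 1L          # 1-based
      b <- qp[run_end[r]] + k             # 1-based inclusive end of last seed
      ab <- xdrop_extend(qi, ti, a, b, d, xdrop = xdrop)
      if (ab[2] < ab[1]) next
      spans[[length(spans) + 1L]] <- ab
    }
    if (length(spans) == 0) next
    # merge overlapping/touching extended spans on the same diagonal
    spans <- spans[order(vapply(spans, `[`, numeric(1), 1L))]
    merged <- list(spans[[1]])
    for (s in spans[-1]) {
      last <- merged[[length(merged)]]
      if (s[1] <= last[2] + 1L) {
        merged[[length(merged)]] <- c(last[1], max(last[2], s[2]))
      } else {
        merged[[length(merged) + 1L]] <- s
      }
    }
    for (ab in merged) {
      A <- ab[1]; B <- ab[2]
      if (B < A) next
      # trim to the maximal-scoring subsegment so a spurious seed merged
      # across a non-homologous gap cannot inflate the hit boundaries
      mvec <- ifelse(qi[A:B] == ti[(A:B) + d], 1, -2)
      cs <- cumsum(mvec)
      mins <- cummin(c(0, cs[-length(cs)]))
      gains <- cs - mins
      end_rel <- which.max(gains)
      start_rel <- which.min(c(0, cs)[seq_len(end_rel)])  # argmin prefix
      B <- A + end_rel - 1L
      A <- A + start_rel - 1L
      len <- B - A + 1L
      if (len < min_hit_len) next
      nmatch <- sum(qi[A:B] == ti[(A:B) + d])
      if (nmatch / len < min_identity) next
      n_out <- n_out + 1L
      if (n_out > nrow(out)) {
        out <- rbind(out, matrix(0L, nrow = nrow(out), ncol = 4L))
      }
      out[n_out, ] <- c(A, B, d, nmatch)
    }
  }
  if (n_out == 0) return(empty_hits())
  A <- out[seq_len(n_out), 1]; B <- out[seq_len(n_out), 2]
  d <- out[seq_len(n_out), 3]; nmatch <- out[seq_len(n_out), 4]
  len <- B - A + 1L
  data.frame(
    query_start = A - 1L, query_end = B, target = tname,
    target_start = A - 1L + d, target_end = B + d, strand = "+",
    length = len, matches = nmatch, identity = nmatch / len,
    score = nmatch - 2L * (len - nmatch), uniqueness = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Local similarity search by seed-and-extend
#'
#' Finds gapless local alignments between a query sequence and a collection
#' of target sequences on both strands. Exact k-mer seeds are grouped by
#' diagonal, merged into runs and extended under an X-drop criterion; hits
#' below the identity threshold are dropped. Placement confidence
#' (`uniqueness`) is the score gap between a hit and the best other hit
#' covering at least half of the same query interval, emulating a
#' mapping-quality filter at the contract level.
#'
#' @param query DNA string.
#' @param targets Named character vector (or `DNAStringSet`) of target
#'   sequences.
#' @param min_identity Minimum fraction of matching bases per hit.
#' @param seed_word Exact seed length in bp.
#' @param min_uniqueness Minimum score gap to the best alternative placement;
#'   set to 0 to keep ambiguous hits.
#' @param both_strands Also search the reverse complement of the query.
#' @param max_seed_gap Maximum gap (bp) between seeds merged into one
#'   diagonal run before extension.
#' @param xdrop X-drop termination threshold for extension.
#' @param min_hit_len Minimum reported hit length (defaults to `seed_word`).
#' @return data.frame of hits with 0-based half-open `query_start`/`query_end`
#'   (always on the forward query), `target`, `target_start`/`target_end`
#'   (forward target coordinates), `strand`, `length`, `matches`, `identity`,
#'   `score` and `uniqueness`.
#' @export
local_hits <- function(query, targets, min_identity = 0.8, seed_word = 5,
                       min_uniqueness = 10, both_strands = TRUE,
                       max_seed_gap = 100, xdrop = 40, min_hit_len = NULL) {
  if (methods::is(targets, "XStringSet")) {
    targets <- setNames(as.character(targets), names(targets))
  }
  if (is.null(names(targets))) {
    names(targets) <- paste0("target", seq_along(targets))
  }
  if (is.null(min_hit_len)) min_hit_len <- seed_word
  nq <- nchar(query)
  if (nq < seed_word) {
    warning("query shorter than seed word; no hits")
    return(empty_hits())
  }
  res <- list()
  qrc <- if (both_strands) revcomp(query) else NULL
  cached <- attr(targets, "sv_seed_index")[[as.character(seed_word)]]
  for (tn in names(targets)) {
    index <- cached[[tn]]
    if (is.null(index)) index <- build_seed_index(targets[[tn]], seed_word)
    h <- hits_one_strand(query, index, tn, seed_word, min_identity,
                         max_seed_gap, xdrop, min_hit_len)
    if (nrow(h)) res[[length(res) + 1L]] <- h
    if (both_strands) {
      hr <- hits_one_strand(qrc, index, tn, seed_word, min_identity,
                            max_seed_gap, xdrop, min_hit_len)
      if (nrow(hr)) {
        # map coordinates back onto the forward query
        qs <- nq - hr$query_end
        qe <- nq - hr$query_start
        hr$query_start <- qs
        hr$query_end <- qe
        hr$strand <- "-"
        res[[length(res) + 1L]] <- hr
      }
    }
  }
  if (length(res) == 0) return(empty_hits())
  hits <- do.call(rbind, res)
  rownames(hits) <- NULL
  # uniqueness: score margin over the best other hit sharing >=50% of the
  # shorter query interval at a different placement
  n <- nrow(hits)
  uniq <- hits$score
  if (n > 1) {
    for (i in seq_len(n)) {
      ov <- pmin(hits$query_end, hits$query_end[i]) -
        pmax(hits$query_start, hits$query_start[i])
      minlen <- pmin(hits$length, hits$length[i])
      cand <- which(ov >= 0.5 * minlen)
      cand <- setdiff(cand, i)
      if (length(cand)) {
        uniq[i] <- hits$score[i] - max(hits$score[cand])
      }
    }
  }
  hits$uniqueness <- uniq
  hits <- hits[hits$uniqueness >= min_uniqueness, , drop = FALSE]
  rownames(hits) <- NULL
  hits[order(hits$query_start, hits$query_end), , drop = FALSE]
}

chain_compatible <- function(prev, nxt, max_overlap) {
  nxt["query_start"] >= prev["query_start"] &&
    nxt["query_end"] > prev["query_end"] &&
    (prev["query_end"] - nxt["query_start"]) <= max_overlap
}

empty_chain <- function(query_len) {
  structure(list(hits = empty_hits(), covered_bases = 0L,
                 coverage = 0, query_len = query_len),
            class = "sv_chain")
}

#' Optimal complementarity chaining of alignment hits
#'
#' Selects the set of hits maximizing the number of distinct query bases
#' covered (the minimum set of non-overlapping alignments spanning the
#' maximum fraction of the query). Hits in a chain must progress strictly
#' along the query; consecutive hits may overlap by at most `max_overlap`
#' bp. Ties are broken toward fewer hits, then higher summed score. Solved
#' exactly by dynamic programming over hits ordered along the query.
#'
#' @param hits data.frame as returned by [local_hits()].
#' @param query_len Query length in bp.
#' @param max_overlap Maximum tolerated query overlap between consecutive
#'   chained hits.
#' @return An `sv_chain`: list with `hits` (the chained subset, in query
#'   order), `covered_bases`, `coverage` and `query_len`.
#' @export
chain_best <- function(hits, query_len, max_overlap = 10) {
  if (is.null(hits) || nrow(hits) == 0) return(empty_chain(query_len))
  o <- order(hits$query_start, hits$query_end)
  hits <- hits[o, , drop = FALSE]
  n <- nrow(hits)
  qs <- hits$query_start; qe <- hits$query_end; sc <- hits$score
  cov <- numeric(n); cnt <- integer(n); tot <- numeric(n); prev <- integer(n)
  for (i in seq_len(n)) {
    cov[i] <- qe[i] - qs[i]; cnt[i] <- 1L; tot[i] <- sc[i]; prev[i] <- 0L
    for (j in seq_len(i - 1L)) {
      if (qs[i] < qs[j] || qe[i] <= qe[j]) next
      if (qe[j] - qs[i] > max_overlap) next
      add <- qe[i] - max(qs[i], qe[j])
      c_cov <- cov[j] + add; c_cnt <- cnt[j] + 1L; c_tot <- tot[j] + sc[i]
      if (c_cov > cov[i] ||
          (c_cov == cov[i] && (c_cnt < cnt[i] ||
                               (c_cnt == cnt[i] && c_tot > tot[i])))) {
        cov[i] <- c_cov; cnt[i] <- c_cnt; tot[i] <- c_tot; prev[i] <- j
      }
    }
  }
  best <- 1L
  for (i in seq_len(n)) {
    if (cov[i] > cov[best] ||
        (cov[i] == cov[best] && (cnt[i] < cnt[best] ||
                                 (cnt[i] == cnt[best] && tot[i] > tot[best])))) {
      best <- i
    }
  }
  path <- integer(0); i <- best
  while (i > 0) { path <- c(i, path); i <- prev[i] }
  out <- hits[path, , drop = FALSE]
  rownames(out) <- NULL
  covered <- interval_union_len(out$query_start, out$query_end)
  structure(list(hits = out, covered_bases = covered,
                 coverage = covered / max(1L, query_len),
                 query_len = query_len),
            class = "sv_chain")
}

#' Exhaustive reference chainer
#'
#' Independent reference implementation of [chain_best()]: depth-first
#' enumeration of every valid chain (same compatibility rules), computing
#' covered bases by explicit interval union. Exponential; intended for
#' validating the dynamic program on small instances.
#'
#' @inheritParams chain_best
#' @return Same structure as [chain_best()].
#' @export
chain_best_exhaustive <- function(hits, query_len, max_overlap = 10) {
  if (is.null(hits) || nrow(hits) == 0) return(empty_chain(query_len))
  o <- order(hits$query_start, hits$query_end)
  hits <- hits[o, , drop = FALSE]
  n <- nrow(hits)
  qs <- hits$query_start; qe <- hits$query_end; sc <- hits$score
  best <- list(cov = -1, cnt = Inf, tot = -Inf, path = integer(0))
  consider <- function(path) {
    cov <- interval_union_len(qs[path], qe[path])
    cnt <- length(path); tot <- sum(sc[path])
    if (cov > best$cov ||
        (cov == best$cov && (cnt < best$cnt ||
                             (cnt == best$cnt && tot > best$tot)))) {
      best <<- list(cov = cov, cnt = cnt, tot = tot, path = path)
    }
  }
  recurse <- function(idx, path) {
    if (idx > n) {
      if (length(path)) consider(path)
      return(invisible(NULL))
    }
    ok <- length(path) == 0
    if (!ok) {
      j <- path[length(path)]
      ok <- qs[idx] >= qs[j] && qe[idx] > qe[j] &&
        (qe[j] - qs[idx]) <= max_overlap
    }
    if (ok) recurse(idx + 1L, c(path, idx))
    recurse(idx + 1L, path)
  }
  recurse(1L, integer(0))
  if (best$cov < 0) return(empty_chain(query_len))
  out <- hits[best$path, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(hits = out, covered_bases = best$cov,
                 coverage = best$cov / max(1L, query_len),
                 query_len = query_len),
            class = "sv_chain")
}
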