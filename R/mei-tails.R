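# Poly(A/T) tail and target-site-duplication detection on insert alleles.

#' Scan for a poly(A/T) tail near one insert end
#'
#' Finds the longest window within `max_offset` bp of the given end whose
#' purity (fraction of the tract base within the window) meets `min_purity`
#' and whose length meets `min_len`. Windows are required to start and end
#' on the tract base; ties are broken toward the smaller offset from the
#' end.
#'
#' @param seq Insert sequence.
#' @param end `"3p"` (default base A) or `"5p"` (default base T).
#' @param base Tract base; defaults by end as above.
#' @param min_len Minimum tract length (bp).
#' @param min_purity Minimum tract purity.
#' @param max_offset Maximum distance of the tract from the given end (bp).
#' @return NULL, or a list (`sv_polytail`) with `kind` (polyA/polyT),
#'   `length`, `purity`, `offset_from_end`, and 0-based half-open
#'   `start`/`end` on `seq`.
#' @export
scan_poly_tail <- function(seq, end = c("3p", "5p"), base = NULL,
                           min_len = 10, min_purity = 0.90, max_offset = 50) {
  end <- match.arg(end)
  if (is.null(base)) base <- if (end == "3p") "A" else "T"
  n <- nchar(seq)
  if (n == 0) return(NULL)
  flip <- end == "5p"
  s <- if (flip) paste(rev(strsplit(seq, "")[[1]]), collapse = "") else seq
  x <- as.integer(strsplit(s, "")[[1]] == base)
  cs <- c(0L, cumsum(x))
  best <- NULL
  j_lo <- max(1L, n - as.integer(max_offset))
  for (j in n:j_lo) {
    if (x[j] == 0L) next
    i_cand <- which(x[1:j] == 1L)
    len <- j - i_cand + 1L
    pur <- (cs[j + 1L] - cs[i_cand]) / len
    ok <- len >= min_len & pur >= min_purity
    if (!any(ok)) next
    i0 <- i_cand[ok][1]  # smallest i -> longest window ending at j
    len0 <- j - i0 + 1L
    if (is.null(best) || len0 > best$length) {
      best <- list(length = len0, purity = (cs[j + 1L] - cs[i0]) / len0,
                   offset_from_end = n - j, i = i0, j = j)
    }
  }
  if (is.null(best)) return(NULL)
  if (flip) {
    start0 <- n - best$j
    end0 <- n - best$i + 1L
    off <- best$offset_from_end
  } else {
    start0 <- best$i - 1L
    end0 <- best$j
    off <- best$offset_from_end
  }
  structure(list(kind = if (base == "A") "polyA" else "polyT",
                 length = best$length, purity = best$purity,
                 offset_from_end = off, start = start0, end = end0),
            class = "sv_polytail")
}

# All maximal qualifying base tracts anywhere in seq (used to locate the
# internal poly(A) separating an element from a 3' transduced segment).
# Returns data.frame(start, end) 0-based half-open, sorted, non-overlapping.
poly_tracts <- function(seq, base = "A", min_len = 10, min_purity = 0.90,
                        max_tract = 100L) {
  n <- nchar(seq)
  if (n < min_len) return(data.frame(start = integer(0), end = integer(0)))
  x <- as.integer(strsplit(seq, "")[[1]] == base)
  cs <- c(0L, cumsum(x))
  need <- ceiling(min_purity * min_len)
  # candidate window ends: dense in base over the trailing min_len bases
  js <- which(x == 1L)
  js <- js[js >= min_len & (cs[js + 1L] - cs[pmax(0L, js - min_len) + 1L]) >= need]
  out <- list()
  for (j in js) {
    i_lo <- max(1L, j - max_tract + 1L)
    i_cand <- i_lo:j
    i_cand <- i_cand[x[i_cand] == 1L]
    len <- j - i_cand + 1L
    pur <- (cs[j + 1L] - cs[i_cand]) / len
    ok <- len >= min_len & pur >= min_purity
    if (!any(ok)) next
    i0 <- i_cand[ok][1]
    out[[length(out) + 1L]] <- c(i0 - 1L, j)
  }
  if (length(out) == 0) return(data.frame(start = integer(0), end = integer(0)))
  m <- do.call(rbind, out)
  df <- data.frame(start = m[, 1], end = m[, 2])
  df <- df[order(df$start, -df$end), , drop = FALSE]
  # merge overlapping windows into maximal tracts
  keep <- list(df[1, ])
  for (i in seq_len(nrow(df))[-1]) {
    last <- keep[[length(keep)]]
    if (df$start[i] <= last$end) {
      keep[[length(keep)]]$end <- max(last$end, df$end[i])
    } else {
      keep[[length(keep) + 1L]] <- df[i, ]
    }
  }
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  out
}

#' Detect a target site duplication at an insertion
#'
#' The TSD is the longest exact terminal match between one insert end and
#' the immediately adjacent reference sequence: the insert prefix against
#' the downstream flank (TSD copy at the insert 5' end) or the insert suffix
#' against the upstream flank (TSD copy at the insert 3' end). Ties are
#' resolved toward the longer match, then toward the 3' end.
#'
#' @param alt_seq Insert sequence (without the VCF anchor base).
#' @param ref_up Reference flank immediately upstream of the integration
#'   position.
#' @param ref_down Reference flank immediately downstream.
#' @param max_len Maximum TSD length searched.
#' @return NULL (no exact terminal match) or a list (`sv_tsd`) with
#'   `sequence`, `length` and `end` ("5p"/"3p": which insert end carries the
#'   duplicate copy).
#' @export
find_tsd <- function(alt_seq, ref_up, ref_down, max_len = 50) {
  k5 <- lcp_len(alt_seq, ref_down, cap = max_len)
  k3 <- lcs_len(alt_seq, ref_up, cap = max_len)
  if (k5 == 0 && k3 == 0) return(NULL)
  if (k3 >= k5) {
    n <- nchar(alt_seq)
    structure(list(sequence = substr(alt_seq, n - k3 + 1L, n),
                   length = k3, end = "3p"), class = "sv_tsd")
  } else {
    structure(list(sequence = substr(alt_seq, 1L, k5),
                   length = k5, end = "5p"), class = "sv_tsd")
  }
}

#' Orient an insert and trim its TSD and terminal tail
#'
#' Removes the TSD (when given), decides the insert orientation from the
#' terminal tails (a 5' poly(T) stronger than any 3' poly(A) indicates a
#' minus-strand integration and triggers reverse complementation), and trims
#' the terminal tail. The returned body is in forward orientation.
#'
#' @param alt_seq Insert sequence (anchor base removed).
#' @param tsd Optional `sv_tsd` from [find_tsd()].
#' @param min_len,min_purity,max_offset Tail thresholds, see
#'   [scan_poly_tail()].
#' @return List with `body`, `orientation` ("+"/"-"), `tail` (the trimmed
#'   `sv_polytail`, re-oriented, or NULL), `tsd`, and `trimmed_tail_bases`
#'   (bases removed from the tail end, including any offset bases).
#' @export
orient_and_trim <- function(alt_seq, tsd = NULL, min_len = 10,
                            min_purity = 0.90, max_offset = 50) {
  seq <- alt_seq
  if (!is.null(tsd) && tsd$length > 0) {
    n <- nchar(seq)
    seq <- if (tsd$end == "3p") substr(seq, 1L, n - tsd$length) else
      substr(seq, tsd$length + 1L, n)
  }
  tail_a <- scan_poly_tail(seq, "3p", min_len = min_len,
                           min_purity = min_purity, max_offset = max_offset)
  tail_t <- scan_poly_tail(seq, "5p", min_len = min_len,
                           min_purity = min_purity, max_offset = max_offset)
  len_a <- if (is.null(tail_a)) 0L else tail_a$length
  len_t <- if (is.null(tail_t)) 0L else tail_t$length
  orientation <- if (len_t > len_a) "-" else "+"
  if (orientation == "-") {
    seq <- revcomp(seq)
    n <- nchar(seq)
    # the 5' polyT becomes a 3' polyA on the flipped sequence
    tail <- structure(list(kind = "polyA", length = tail_t$length,
                           purity = tail_t$purity,
                           offset_from_end = tail_t$offset_from_end,
                           start = n - tail_t$end, end = n - tail_t$start),
                      class = "sv_polytail")
  } else {
    tail <- tail_a
  }
  trimmed <- 0L
  if (!is.null(tail)) {
    trimmed <- nchar(seq) - tail$start
    seq <- substr(seq, 1L, tail$start)
  }
  list(body = seq, orientation = orientation, tail = tail, tsd = tsd,
       trimmed_tail_bases = trimmed)
}
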