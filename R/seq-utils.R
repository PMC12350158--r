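#' @keywords internal
"_PACKAGE"

#' @importFrom stats setNames binom.test rpois runif rbinom
#' @importFrom utils adist
#' @importFrom methods is
NULL

# Sequences are plain uppercase character scalars (alphabet A,C,G,T,N); a
# genome is a named character vector of contigs. Coordinates are 0-based
# half-open everywhere inside the package; the VCF layer converts.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A,C,G,T,N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(out, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Extract a genome interval (0-based, half-open)
#'
#' @param genome Named character vector of contig sequences.
#' @param chrom Contig name.
#' @param start,end 0-based half-open interval; clipped to contig bounds.
#' @return The interval sequence as a character scalar.
#' @export
genome_seq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    stop("contig not found in genome: ", chrom)
  }
  start <- max(0L, as.integer(start))
  end <- as.integer(end)
  if (end <= start) return("")
  # substr clips at the contig end, so no length lookup is needed
  substr(genome[[chrom]], start + 1L, end)
}

#' Read a genome FASTA into the internal representation
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase contig sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of contig sequences.
#' @param path Output FASTA path.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unname(genome))
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# Longest common prefix length of two strings, optionally capped.
lcp_len <- function(a, b, cap = Inf) {
  n <- min(nchar(a), nchar(b), cap)
  if (n == 0) return(0L)
  ai <- utf8ToInt(substr(a, 1L, n))
  bi <- utf8ToInt(substr(b, 1L, n))
  neq <- which(ai != bi)
  if (length(neq) == 0) n else neq[1] - 1L
}

# Longest common suffix length of two strings, optionally capped.
lcs_len <- function(a, b, cap = Inf) {
  na <- nchar(a); nb <- nchar(b)
  n <- min(na, nb, cap)
  if (n == 0) return(0L)
  ai <- utf8ToInt(substr(a, na - n + 1L, na))
  bi <- utf8ToInt(substr(b, nb - n + 1L, nb))
  neq <- which(rev(ai) != rev(bi))
  if (length(neq) == 0) n else neq[1] - 1L
}

# Evaluate expr with a temporary RNG seed when seed is non-NULL.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# Union length of a set of 0-based half-open intervals.
interval_union_len <- function(starts, ends) {
  if (length(starts) == 0) return(0L)
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  total <- 0L
  cur_s <- starts[1]; cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= cur_e) {
      cur_e <- max(cur_e, ends[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- starts[i]; cur_e <- ends[i]
    }
  }
  total + (cur_e - cur_s)
}
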