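# SV records are rows of a plain data.frame (class "sv_records"):
#   id, chrom, start, end, svtype, ref, alt, svlen, unresolvable
# start/end are 0-based half-open over the REF allele span; svtype is derived
# from allele lengths (DEL / INS / COMPLEX). Genotypes, when present, live in
# a list-column `gt` of named character vectors ("0|1" style).

#' Construct an SV record table
#'
#' @param id,chrom Character vectors.
#' @param start 0-based start of the REF allele span.
#' @param ref,alt Allele sequences (uppercase A,C,G,T,N); symbolic ALT
#'   alleles (angle-bracket tokens or breakends) mark the record
#'   unresolvable.
#' @param gt Optional list of named genotype vectors per record.
#' @return data.frame of class `sv_records`.
#' @export
sv_records <- function(id, chrom, start, ref, alt, gt = NULL) {
  ref <- toupper(ref); alt <- toupper(alt)
  symbolic <- function(x) {
    grepl("[<>]", x) | grepl("[", x, fixed = TRUE) | grepl("]", x, fixed = TRUE)
  }
  unresolvable <- symbolic(alt) | symbolic(ref)
  nref <- nchar(ref); nalt <- nchar(alt)
  svtype <- rep(NA_character_, length(id))
  ok <- !unresolvable
  svtype[ok & nref > 1 & nalt == 1] <- "DEL"
  svtype[ok & nalt > 1 & nref == 1] <- "INS"
  svtype[ok & nalt > 1 & nref > 1] <- "COMPLEX"
  svlen <- abs(nalt - nref)
  df <- data.frame(
    id = as.character(id), chrom = as.character(chrom),
    start = as.integer(start), end = as.integer(start) + nref,
    svtype = svtype, ref = ref, alt = alt, svlen = as.integer(svlen),
    unresolvable = unresolvable, stringsAsFactors = FALSE
  )
  if (!is.null(gt)) df$gt <- gt
  class(df) <- c("sv_records", "data.frame")
  df
}

#' Inserted / deleted allele sequence of a record
#'
#' For INS returns the inserted bases (ALT minus the shared anchor base),
#' for DEL the deleted bases; for COMPLEX the longer allele minus the anchor.
#'
#' @param rec One-row slice of an `sv_records` table (or a list).
#' @return Character scalar.
#' @export
sv_allele_seq <- function(rec) {
  if (isTRUE(rec$unresolvable)) return(NA_character_)
  if (identical(rec$svtype, "DEL")) return(substr(rec$ref, 2L, nchar(rec$ref)))
  if (identical(rec$svtype, "INS")) return(substr(rec$alt, 2L, nchar(rec$alt)))
  if (nchar(rec$alt) >= nchar(rec$ref)) {
    substr(rec$alt, 2L, nchar(rec$alt))
  } else {
    substr(rec$ref, 2L, nchar(rec$ref))
  }
}

# carriers of the alternate allele from a genotype vector like c(S1="0|1")
gt_carriers <- function(gt) {
  if (is.null(gt) || length(gt) == 0) return(character(0))
  has_alt <- vapply(strsplit(gt, "[/|]"), function(a) any(a == "1"),
                    logical(1))
  names(gt)[has_alt & !is.na(has_alt)]
}

#' Alternate allele frequency per record
#'
#' @param records `sv_records` table with a `gt` list-column.
#' @return Numeric vector of allele frequencies (NA without genotypes).
#' @export
sv_allele_freq <- function(records) {
  if (is.null(records$gt)) return(rep(NA_real_, nrow(records)))
  vapply(records$gt, function(g) {
    if (is.null(g) || length(g) == 0) return(NA_real_)
    al <- unlist(strsplit(g, "[/|]"))
    al <- al[al %in% c("0", "1")]
    if (length(al) == 0) return(NA_real_)
    mean(al == "1")
  }, numeric(1))
}
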