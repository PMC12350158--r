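# Consensus element database: named sequences plus a metadata table mapping
# each entry to an element family and (for multi-part elements such as SVA)
# a part order. Real Alu/L1/SVA/LTR consensus files are user-supplied; the
# test suite uses synthetic stand-ins from synthetic_consensus_db().

#' Build a consensus database object
#'
#' @param seqs Named character vector of consensus sequences. The
#'   mitochondrial entry is stored as given; circularity is handled at
#'   alignment time.
#' @param meta data.frame with columns `name`, `family` (Alu, L1, SVA, LTR,
#'   ERVK, MT), optional `part_order` (integer; 3'-most part has the largest
#'   value) and optional `subfamily`.
#' @return `sv_consensus_db` list.
#' @export
consensus_db <- function(seqs, meta) {
  stopifnot(all(meta$name %in% names(seqs)))
  if (is.null(meta$part_order)) meta$part_order <- 1L
  if (is.null(meta$subfamily)) meta$subfamily <- NA_character_
  seqs <- index_targets(seqs, 8)
  structure(list(seqs = seqs, meta = meta), class = "sv_consensus_db")
}

#' Read a consensus database from FASTA + metadata TSV
#'
#' @param fasta FASTA of consensus sequences.
#' @param meta_tsv Tab-separated table with columns `name`, `family`,
#'   optional `part_order`, `subfamily`.
#' @return `sv_consensus_db`.
#' @export
read_consensus_db <- function(fasta, meta_tsv) {
  seqs <- read_genome_fasta(fasta)
  meta <- utils::read.delim(meta_tsv, stringsAsFactors = FALSE)
  consensus_db(seqs, meta)
}

#' Write a consensus database to FASTA + metadata TSV
#'
#' @param db `sv_consensus_db`.
#' @param fasta,meta_tsv Output paths.
#' @export
write_consensus_db <- function(db, fasta, meta_tsv) {
  write_genome_fasta(db$seqs, fasta)
  utils::write.table(db$meta, meta_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta, meta_tsv))
}

db_family <- function(db, name) {
  db$meta$family[match(name, db$meta$name)]
}

# total consensus length of a family (sum over parts)
db_family_len <- function(db, family) {
  nm <- db$meta$name[db$meta$family == family]
  sum(nchar(db$seqs[nm]))
}

# name and length of the 3'-most part of a family
db_last_part <- function(db, family) {
  m <- db$meta[db$meta$family == family, , drop = FALSE]
  m <- m[order(m$part_order), , drop = FALSE]
  nm <- m$name[nrow(m)]
  list(name = nm, length = nchar(db$seqs[[nm]]))
}

MEI_FAMILIES <- c("Alu", "L1", "SVA")
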