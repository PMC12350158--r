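# VCF I/O. Reading goes through vcfR; 1-based VCF positions are converted to
# the internal 0-based half-open convention at this boundary only.
# Multiallelic records are split into one sv_record per ALT allele at parse
# time and re-joined (by shared position/REF) when writing.

#' Parse sequence-resolved SVs from a VCF
#'
#' @param path VCF file (plain text or gzipped).
#' @param reference Optional genome (named character vector); when supplied,
#'   every REF allele is checked against the reference sequence and a
#'   mismatch raises an error naming the position.
#' @return `sv_records` table in 0-based half-open coordinates. Symbolic ALT
#'   alleles (e.g. `<INV>`) are retained but flagged `unresolvable`.
#' @export
parse_sv_vcf <- function(path, reference = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fm <- vcfR::getFIX(v)
  if (!is.matrix(fm)) {
    # single-record VCFs come back as a named vector
    fm <- matrix(fm, nrow = 1, dimnames = list(NULL, names(fm)))
  }
  fix <- as.data.frame(fm, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(sv_records(character(0), character(0), integer(0),
                      character(0), character(0)))
  }
  gt_mat <- NULL
  if (ncol(v@gt) > 1) {
    gt_mat <- vcfR::extract.gt(v, element = "GT")
    if (!is.matrix(gt_mat)) {
      gt_mat <- matrix(gt_mat, nrow = 1, dimnames = list(NULL, names(gt_mat)))
    }
  }
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0("sv", which(is.na(fix$ID) | fix$ID == "."))
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      id <- if (length(alts) > 1) paste0(ids[i], "_", k) else ids[i]
      gt <- NULL
      if (!is.null(gt_mat)) {
        # keep sample names even when subsetting drops to a scalar
        g <- setNames(as.character(gt_mat[i, ]), colnames(gt_mat))
        if (length(alts) > 1) {
          # per-allele view of a multiallelic genotype: allele k -> 1
          g <- vapply(g, function(x) {
            if (is.na(x)) return(NA_character_)
            sep <- if (grepl("|", x, fixed = TRUE)) "|" else "/"
            al <- strsplit(x, "[/|]")[[1]]
            al <- ifelse(al == as.character(k), "1",
                         ifelse(al == ".", ".", "0"))
            paste(al, collapse = sep)
          }, character(1))
        }
        gt <- g
      }
      rows[[length(rows) + 1L]] <- list(
        id = id, chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k], gt = gt
      )
    }
  }
  recs <- sv_records(
    id = vapply(rows, `[[`, character(1), "id"),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    start = vapply(rows, `[[`, integer(1), "pos") - 1L,
    ref = vapply(rows, `[[`, character(1), "ref"),
    alt = vapply(rows, `[[`, character(1), "alt"),
    gt = if (is.null(gt_mat)) NULL else lapply(rows, `[[`, "gt")
  )
  if (!is.null(reference)) {
    for (i in seq_len(nrow(recs))) {
      if (recs$unresolvable[i]) next
      if (!recs$chrom[i] %in% names(reference)) {
        stop("VCF contig missing from reference: ", recs$chrom[i])
      }
      obs <- genome_seq(reference, recs$chrom[i], recs$start[i], recs$end[i])
      if (!identical(obs, recs$ref[i])) {
        stop(sprintf("REF allele mismatch at %s:%d", recs$chrom[i],
                     recs$start[i] + 1L))
      }
    }
  }
  recs
}

#' Write SV records to a VCF
#'
#' Records split from one multiallelic site (same chrom, start and REF, ids
#' sharing a `_k` suffix stem) are re-joined into a single VCF line.
#'
#' @param records `sv_records` table.
#' @param path Output path (plain-text VCF).
#' @param genome Optional genome for contig header lines.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(records, path, genome = NULL) {
  has_gt <- !is.null(records$gt) &&
    any(vapply(records$gt, function(g) !is.null(g) && length(g) > 0, logical(1)))
  samples <- character(0)
  if (has_gt) {
    samples <- unique(unlist(lapply(records$gt, names)))
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svkit",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">"
  )
  if (!is.null(genome)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(genome),
                          nchar(genome)))
  }
  if (has_gt) {
    hdr <- c(hdr,
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  }
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (has_gt) cols <- c(cols, "FORMAT", samples)
  hdr <- c(hdr, paste(cols, collapse = "\t"))

  # group multiallelic siblings back together
  stem <- sub("_[0-9]+$", "", records$id)
  key <- paste(records$chrom, records$start, records$ref, stem, sep = "\r")
  lines <- character(0)
  for (kk in unique(key)) {
    idx <- which(key == kk)
    r1 <- records[idx[1], ]
    alts <- records$alt[idx]
    info <- sprintf("SVTYPE=%s;SVLEN=%d",
                    ifelse(is.na(r1$svtype), "NA", r1$svtype), r1$svlen)
    fields <- c(r1$chrom, r1$start + 1L,
                if (length(idx) > 1) stem[idx[1]] else r1$id,
                r1$ref, paste(alts, collapse = ","), ".", "PASS", info)
    if (has_gt) {
      gts <- vapply(samples, function(s) {
        # recombine per-allele genotypes into a multiallelic GT
        per <- lapply(seq_along(idx), function(k) records$gt[[idx[k]]][[s]])
        if (all(vapply(per, is.null, logical(1)))) return("./.")
        base <- per[[1]]
        if (is.na(base)) return("./.")
        sep <- if (grepl("|", base, fixed = TRUE)) "|" else "/"
        al <- strsplit(base, "[/|]")[[1]]
        for (k in seq_along(idx)[-1]) {
          alk <- strsplit(per[[k]], "[/|]")[[1]]
          al[alk == "1"] <- as.character(k)
        }
        paste(al, collapse = sep)
      }, character(1))
      fields <- c(fields, "GT", gts)
    }
    lines <- c(lines, paste(fields, collapse = "\t"))
  }
  ord <- order(vapply(strsplit(lines, "\t"), `[`, character(1), 1),
               as.integer(vapply(strsplit(lines, "\t"), `[`, character(1), 2)))
  writeLines(c(hdr, lines[ord]), path)
  invisible(path)
}
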