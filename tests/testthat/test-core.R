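# Coordinate conventions, VCF I/O, duplicate marking, callset matching and
# trio consistency.

test_that("VCF parsing derives types and 0-based coordinates", {
  g <- fixture_genome()
  ref61 <- genome_seq(g, "chrS", 100, 161)
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrS>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"),
    paste(c("chrS", "101", "del1", ref61, substr(ref61, 1, 1), ".", "PASS",
            "."), collapse = "\t"),
    paste(c("chrS", "201", "inv1", genome_seq(g, "chrS", 200, 201), "<INV>",
            ".", "PASS", "."), collapse = "\t")
  ), vcf)
  recs <- parse_sv_vcf(vcf, reference = g)
  expect_equal(recs$start[1], 100L)
  expect_equal(recs$svtype[1], "DEL")
  expect_equal(recs$svlen[1], 60L)
  expect_true(recs$unresolvable[2])
  expect_true(is.na(recs$svtype[2]))
})

test_that("REF mismatches and missing contigs are errors naming the site", {
  g <- fixture_genome()
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"),
    paste(c("chrS", "501", "x", "NNNN", "N", ".", "PASS", "."),
          collapse = "\t")
  ), vcf)
  expect_error(parse_sv_vcf(vcf, reference = g), "501")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"),
    paste(c("chrZ", "11", "x", "A", "AT", ".", "PASS", "."), collapse = "\t")
  ), vcf)
  expect_error(parse_sv_vcf(vcf, reference = g), "chrZ")
})

test_that("write/parse round trip is the identity, genotypes included", {
  set.seed(11)
  g <- fixture_genome()
  starts <- c(1000L, 5000L, 9000L)
  recs <- sv_records(
    id = c("a", "b", "c"), chrom = "chrS", start = starts,
    ref = vapply(starts, function(s) genome_seq(g, "chrS", s, s + 1), ""),
    alt = vapply(starts, function(s)
      paste0(genome_seq(g, "chrS", s, s + 1), rdna(80)), ""),
    gt = list(c(S1 = "0|1", S2 = "0/0"), c(S1 = "1|1", S2 = "./."),
              c(S1 = "0|0", S2 = "0|1"))
  )
  path <- tempfile(fileext = ".vcf")
  write_sv_vcf(recs, path, genome = g)
  back <- parse_sv_vcf(path, reference = g)
  expect_identical(back[, c("id", "chrom", "start", "end", "svtype", "ref",
                            "alt", "svlen")],
                   recs[, c("id", "chrom", "start", "end", "svtype", "ref",
                            "alt", "svlen")])
  expect_identical(unname(back$gt[[1]]), unname(recs$gt[[1]]))
  # second round trip is byte-stable in content
  path2 <- tempfile(fileext = ".vcf")
  write_sv_vcf(back, path2, genome = g)
  expect_identical(readLines(path), readLines(path2))
})

test_that("multiallelic records split at parse time and re-join at write", {
  vcf <- tempfile(fileext = ".vcf")
  ins1 <- paste0("A", strrep("CT", 30))
  ins2 <- paste0("A", strrep("GA", 40))
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1"), collapse = "\t"),
    paste(c("chr1", "11", "m", "A", paste(ins1, ins2, sep = ","), ".",
            "PASS", ".", "GT", "1|2"), collapse = "\t")
  ), vcf)
  recs <- parse_sv_vcf(vcf)
  expect_equal(nrow(recs), 2L)
  expect_equal(recs$id, c("m_1", "m_2"))
  expect_equal(unname(recs$gt[[1]][["S1"]]), "1|0")
  expect_equal(unname(recs$gt[[2]][["S1"]]), "0|1")
  out <- tempfile(fileext = ".vcf")
  write_sv_vcf(recs, out)
  body <- grep("^#", readLines(out), invert = TRUE, value = TRUE)
  expect_length(body, 1L)
  expect_match(body, "1|2")
})

test_that("duplicate marking applies all four rules with one representative", {
  allele <- strrep("ACGGT", 20)
  mk <- function(id, start, allele, carriers = c("s1", "s2")) {
    gt <- setNames(rep("0/0", 4), paste0("s", 1:4))
    gt[carriers] <- "0/1"
    sv_records(id = id, chrom = "chr1", start = start, ref = "G",
               alt = paste0("G", allele), gt = list(gt))
  }
  recs <- rbind(
    mk("a", 1000L, allele), mk("b", 1000L, allele),        # exact duplicates
    mk("c", 1600L, allele),                                # offset 600
    mk("d", 1000L, substr(allele, 1, 45))                  # size ratio 0.45
  )
  marked <- mark_duplicate_sites(recs)
  expect_equal(sort(marked$id[!marked$duplicate]), c("a", "c", "d"))
  expect_true(marked$duplicate[marked$id == "b"])
  # idempotence
  again <- mark_duplicate_sites(marked[!marked$duplicate,
                                       names(recs), drop = FALSE])
  expect_false(any(again$duplicate))
  # disjoint carriers break the carrier rule
  recs2 <- rbind(mk("a", 1000L, allele, c("s1", "s2")),
                 mk("b", 1000L, allele, c("s3", "s4")))
  marked2 <- mark_duplicate_sites(recs2)
  expect_false(any(marked2$duplicate))
})

test_that("callset matching honours offset, ratio and divergence bounds", {
  allele <- strrep("TTAGC", 20)
  mk <- function(id, start, allele) {
    sv_records(id = id, chrom = "chr1", start = start, ref = "C",
               alt = paste0("C", allele))
  }
  base <- rbind(mk("a", 1000L, allele), mk("b", 5000L, allele),
                mk("c", 9000L, allele))
  comp <- rbind(mk("a2", 1050L, allele),                    # offset 50: match
                mk("b2", 5060L, allele),                    # offset 60: no
                mk("c2", 9000L, substr(allele, 1, 79)))     # ratio 0.79: no
  res <- match_callsets(base, comp)
  expect_equal(res$base$matched, c(TRUE, FALSE, FALSE))
  # identity matching is bijective
  self <- match_callsets(base, base)
  expect_true(all(self$base$matched))
  expect_equal(nrow(self$links), nrow(base))
  # empty comparison set leaves everything unmatched without error
  none <- match_callsets(base, base[0, ])
  expect_false(any(none$base$matched))
})

test_that("Mendelian consistency agrees with exhaustive transmission
           enumeration over all 27 biallelic trio combinations", {
  gts <- c("0/0", "0/1", "1/1")
  combos <- expand.grid(f = gts, m = gts, c = gts,
                        stringsAsFactors = FALSE)
  oracle <- apply(combos, 1, function(x) {
    fa <- strsplit(x[["f"]], "/")[[1]]
    mo <- strsplit(x[["m"]], "/")[[1]]
    ch <- sort(strsplit(x[["c"]], "/")[[1]])
    any(vapply(fa, function(a1) any(vapply(mo, function(a2)
      identical(sort(c(a1, a2)), ch), logical(1))), logical(1)))
  })
  res <- mendelian_rate(data.frame(site_id = seq_len(27),
                                   father = combos$f, mother = combos$m,
                                   child = combos$c))
  expect_equal(unname(res$status == "consistent"), unname(oracle))
  expect_equal(res$consistent + res$inconsistent, 27L)
  # missing genotypes are untested and excluded from the denominator
  res2 <- mendelian_rate(data.frame(
    site_id = 1:3, father = c("./.", "0/1", "0/0"),
    mother = c("0/0", "0/0", "0/0"), child = c("0/1", "0/0", "1/1")
  ))
  expect_equal(res2$untested, 1L)
  expect_equal(res2$rate, 0.5)
  expect_true(is.na(mendelian_rate(data.frame(
    site_id = 1, father = "./.", mother = "0/0", child = "0/0"
  ))$rate))
})

test_that("allele divergence is normalized unit-cost edit distance", {
  expect_equal(allele_divergence("ACGT", "ACGT"), 0)
  expect_equal(allele_divergence("AAAA", "TTTT"), 1)
  expect_equal(allele_divergence(strrep("A", 100),
                                 paste0(strrep("A", 70), strrep("C", 30))),
               0.3)
})
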