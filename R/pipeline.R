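# Pipeline driver: wires the annotation stages together over on-disk
# inputs (VCF + FASTA + tracks), with TSV/VCF files as the inter-stage
# contract so every stage is independently re-runnable. A manifest with
# checksums makes reruns verifiable.

#' Default run configuration
#'
#' Every threshold of the toolkit, at its default value, in one list;
#' override entries via the `overrides` argument of [run_pipeline()] or a
#' YAML config file.
#'
#' @return Named list of thresholds.
#' @export
default_config <- function() {
  list(
    min_cov = 0.75,
    tail_min_len = 10, tail_min_purity = 0.90, tail_max_offset = 50,
    tsd_max_len = 50,
    td_min_aligned_frac = 0.8,
    dedup_max_offset = 500, dedup_min_size_ratio = 0.5,
    dedup_max_divergence = 0.30, dedup_min_carrier_frac = 0.10,
    match_max_offset = 50, match_min_size_ratio = 0.8,
    match_max_divergence = 0.10,
    junction_cap = 50,
    atlas_buffer = 10000, atlas_min_n = 5, atlas_null_p = 0.5,
    bubble_min_dist = 1000,
    recur_window_snps = 20000, recur_window_cluster = 100000,
    recur_min_maf = 0.10, recur_cut_height = 0.2,
    seed = 1
  )
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the annotation pipeline over a fixture bundle or user inputs
#'
#' Stages: parse the callset, annotate SV classes (mobile elements, VNTRs,
#' duplications), call breakpoint junctions and mechanisms, build the
#' transduction source atlas, and construct pseudo-haplotypes. Outputs are
#' TSV tables plus a manifest listing every file with its md5 checksum; a
#' rerun with the same inputs and seed reproduces identical checksums.
#'
#' @param inputs Named list of paths: `vcf`, `reference`, `consensus_fasta`,
#'   `consensus_meta`, optional `exons`, `repeats`, `sd`, `centromeres`
#'   (BED-like TSVs with 0-based half-open coordinates).
#' @param outdir Output directory (created).
#' @param overrides Named list of threshold overrides (see
#'   [default_config()]).
#' @param stages Character subset of
#'   `c("annotate", "junctions", "atlas", "augment")`.
#' @return Invisible list with the stage outputs and the manifest
#'   data.frame.
#' @export
run_pipeline <- function(inputs, outdir, overrides = list(),
                         stages = c("annotate", "junctions", "atlas",
                                    "augment")) {
  cfg <- utils::modifyList(default_config(), overrides)
  for (f in c("vcf", "reference", "consensus_fasta", "consensus_meta")) {
    if (is.null(inputs[[f]]) || !file.exists(inputs[[f]])) {
      stop("missing input file: ", f,
           if (!is.null(inputs[[f]])) paste0(" (", inputs[[f]], ")") else "")
    }
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  genome <- read_genome_fasta(inputs$reference)
  db <- read_consensus_db(inputs$consensus_fasta, inputs$consensus_meta)
  records <- parse_sv_vcf(inputs$vcf, reference = genome)
  read_track <- function(key) {
    if (is.null(inputs[[key]]) || !file.exists(inputs[[key]])) return(NULL)
    utils::read.delim(inputs[[key]], stringsAsFactors = FALSE)
  }
  exons <- read_track("exons")
  repeats <- read_track("repeats")
  sd <- read_track("sd")
  centro <- read_track("centromeres")
  outputs <- character(0)
  result <- list(config = cfg)

  ann <- NULL
  if ("annotate" %in% stages) {
    ann <- annotate_sv_callset(records, genome, db, exons = exons)
    outputs <- c(outputs, write_tsv(ann, file.path(outdir, "classes.tsv")))
    result$classes <- ann
  }
  if ("junctions" %in% stages) {
    excluded <- if (!is.null(ann)) {
      ann$id[grepl("^(VNTR|DUP_tandem|solo_|partnered|orphan|non_canonical)",
                   ann$class)]
    } else character(0)
    jc <- annotate_junctions(records, genome, excluded_ids = excluded,
                             repeat_track = repeats, sd_track = sd)
    outputs <- c(outputs, write_tsv(jc, file.path(outdir, "junctions.tsv")))
    result$junctions <- jc
  }
  if ("atlas" %in% stages && !is.null(ann) && nrow(ann)) {
    td <- ann[!is.na(ann$td_side) & !is.na(ann$td_source_start), ,
              drop = FALSE]
    if (nrow(td)) {
      tdf <- data.frame(sv_id = td$id, side = td$td_side,
                        chrom = td$td_source_chrom,
                        start = td$td_source_start, end = td$td_source_end,
                        stringsAsFactors = FALSE)
      atlas <- build_source_atlas(tdf, buffer = cfg$atlas_buffer,
                                  min_n = cfg$atlas_min_n,
                                  null_p = cfg$atlas_null_p)
    } else {
      atlas <- data.frame()
    }
    outputs <- c(outputs, write_tsv(atlas, file.path(outdir, "atlas.tsv")))
    result$atlas <- atlas
  }
  if ("augment" %in% stages) {
    g2 <- genome
    recs2 <- records[!is.na(records$svtype), , drop = FALSE]
    if (!is.null(centro) && nrow(centro)) {
      g2 <- mask_regions(g2, centro)
      fl <- filter_masked_records(recs2, centro)
      recs2 <- fl$kept
    }
    phs <- build_pseudohaplotypes(g2, recs2)
    manif <- do.call(rbind, lapply(phs, function(ph) {
      fa <- file.path(outdir, sprintf("pseudohap_group%d.fa", ph$group_id))
      write_genome_fasta(ph$sequences, fa)
      outputs <<- c(outputs, fa)
      data.frame(group_id = ph$group_id,
                 n_members = length(ph$member_ids),
                 members = paste(ph$member_ids, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    outputs <- c(outputs, write_tsv(manif, file.path(outdir, "groups.tsv")))
    result$pseudohaplotypes <- phs
  }
  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  outputs <- c(outputs, cfg_path)
  manifest <- data.frame(
    file = basename(outputs),
    md5 = unname(tools::md5sum(outputs)),
    stringsAsFactors = FALSE
  )
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  result$manifest <- manifest
  invisible(result)
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Generates a genome, consensus database and mixed truth callset and
#' writes them in the standard formats consumed by [run_pipeline()].
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param genome_len Genome length (bp).
#' @param n_mei,n_other Counts of mobile-element and other descriptors.
#' @return Named list of file paths plus the in-memory fixture.
#' @export
write_fixture_bundle <- function(dir, seed = 1, genome_len = 1.5e6,
                                 n_mei = 8, n_other = 8) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulate_genome(genome_len, seed = seed)
  db <- synthetic_consensus_db(seed + 1)
  desc <- c(
    mei_mix_descriptors(n_mei, seed + 2, db),
    with_seed(seed + 4, {
      lapply(seq_len(n_other), function(i) {
        switch((i - 1L) %% 4L + 1L,
          list(type = "vntr",
               motifs = strip_tracts(random_dna(5, 0.5), min_len = 5),
               copies = 40L, filler = 0L),
          list(type = "dup", dup_class = "tandem", dup_len = 300L),
          list(type = "del_repeat_pair", arm_len = 300L, arm_identity = 0.92,
               del_len = 800L, track_mode = "same_class", sd = FALSE),
          list(type = "del_blunt", del_len = 400L)
        )
      })
    })
  )
  fx <- implant_truth_svs(genome, desc, seed = seed + 3, db = db)
  paths <- list(
    reference = file.path(dir, "genome.fa"),
    vcf = file.path(dir, "calls.vcf"),
    consensus_fasta = file.path(dir, "consensus.fa"),
    consensus_meta = file.path(dir, "consensus_meta.tsv"),
    repeats = file.path(dir, "repeats.tsv"),
    sd = file.path(dir, "sd.tsv"),
    exons = file.path(dir, "exons.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_genome_fasta(fx$genome, paths$reference)
  write_sv_vcf(fx$records, paths$vcf, genome = fx$genome)
  write_consensus_db(db, paths$consensus_fasta, paths$consensus_meta)
  write_tsv(fx$tracks$repeats, paths$repeats)
  write_tsv(fx$tracks$sd, paths$sd)
  write_tsv(fx$tracks$exons, paths$exons)
  write_tsv(fx$truth, paths$truth)
  c(paths, list(fixture = fx))
}
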