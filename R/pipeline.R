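#' Pipeline thresholds and settings
#'
#' Collects every thresholded decision of the discovery pipeline in one
#' place. The defaults are the published cutoffs: allele-specific DHS
#' (mean RPKM > 2, every replicate > 1, fold change > 4), oocyte
#' hypo/hypermethylation classes (0-20% / 80-100%), gDMR (>80% / <20%,
#' strict), maternal H3K27me3 bias (RPM > 0.5 with FC > 2 in ICM, > 4 in
#' zygotes), expression (FPKM > 0.5, bias FC > 2, high bias FC > 8, DEG
#' FC > 10, nascent FDR < 0.05 with FPKM > 2 and FC > 2), and SNP-read
#' minima (20; 10 in the demethylase-injection context). The original
#' defaults travel with the object in the `paper_defaults` attribute, so
#' any override is visible next to the value it replaced.
#'
#' @param ... Named overrides of the defaults listed above.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    dhs_mean_min = 2, dhs_rep_min = 1, dhs_fc_min = 4,
    meth_hypo_max = 0.2, meth_hyper_min = 0.8,
    gdmr_hyper_min = 0.8, gdmr_hypo_max = 0.2,
    chip_rpm_min = 0.5, chip_fc_icm = 2, chip_fc_zygote = 4,
    expressed_min = 0.5, bias_fc = 2, high_bias_fc = 8,
    deg_fc = 10, nascent_fdr = 0.05, nascent_fpkm = 2, nascent_fc = 2,
    min_snp_reads = 20, min_snp_reads_injection = 10,
    rescue_wt_mat_min = 1, rescue_wt_fc_max = 2,
    mapq_max_removed = 10,
    sex_chroms = c("chrX", "chrY"),
    cross_direction = "BxP"
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop(sprintf("unknown config field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, overrides)
  attr(cfg, "paper_defaults") <- defaults
  class(cfg) <- "pipeline_config"
  cfg
}

#' Simulate a complete multi-omic dataset
#'
#' Runs every generator over one planted truth: allelic accessibility
#' counts for all six library types, expression tables for the 2-cell and
#' morula sample types (ERCC rows included), SNP-bearing reads with their
#' strain SNP table, oocyte/sperm methylomes, and allelic H3K27me3 tables
#' for zygote and ICM (plus the Kdm6b-WT/MUT ICM arms). With `outdir` set,
#' all tables are also written as plain-text files (BED/TSV) re-readable
#' by the package's own readers.
#'
#' @param config A [generator_config()].
#' @param outdir Optional output directory.
#' @return A named list (`truth`, `dhs`, `expression`, `reads`, `snps`,
#'   `methylomes`, `chip`, `genes`) — the in-memory bundle consumed by
#'   [run_pipeline()].
#' @export
simulate_dataset <- function(config, outdir = NULL) {
  truth <- generate_truth(config)
  dhs <- dplyr::bind_rows(lapply(dhs_conditions, function(cond) {
    generate_dhs_counts(truth, config, cond)
  }))
  expression <- dplyr::bind_rows(lapply(expression_stages, function(st) {
    generate_expression(truth, config, st)
  }))
  rd <- generate_reads(truth, config)
  meth <- generate_methylomes(truth, config)
  chip <- dplyr::bind_rows(
    generate_chip(truth, config, "zygote"),
    generate_chip(truth, config, "icm"),
    dplyr::mutate(generate_chip(truth, config, "icm", kdm6b = "wt"),
                  stage = "icm_kdm6b_wt"),
    dplyr::mutate(generate_chip(truth, config, "icm", kdm6b = "mut"),
                  stage = "icm_kdm6b_mut")
  )
  genes <- truth[, c("gene_id", "chrom", "tss", "strand", "exonic_length")]
  bundle <- list(truth = truth, dhs = dhs, expression = expression,
                 reads = rd$reads, snps = rd$snps, methylomes = meth,
                 chip = chip, genes = genes)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_bed(dplyr::transmute(truth, .data$chrom, .data$start, .data$end,
                               name = .data$locus_id),
              file.path(outdir, "loci.bed"))
    write_tsv_lf(truth, file.path(outdir, "truth.tsv"))
    write_tsv_lf(dhs, file.path(outdir, "dhs_counts.tsv"))
    write_tsv_lf(expression, file.path(outdir, "expression_counts.tsv"))
    flat_reads <- rd$reads |>
      dplyr::mutate(
        snp_pos = vapply(.data$snp_pos, paste, "", collapse = ","),
        snp_obs = vapply(.data$snp_obs, paste, "", collapse = ","))
    write_tsv_lf(flat_reads, file.path(outdir, "reads.tsv"))
    write_tsv_lf(rd$snps, file.path(outdir, "snps.tsv"))
    write_tsv_lf(meth$oocyte, file.path(outdir, "meth_oocyte.tsv"))
    write_tsv_lf(meth$sperm, file.path(outdir, "meth_sperm.tsv"))
    write_tsv_lf(chip, file.path(outdir, "chip.tsv"))
    write_tsv_lf(genes, file.path(outdir, "genes.tsv"))
  }
  bundle
}

#' Load a simulated dataset directory back into a bundle
#'
#' Inverse of [simulate_dataset()]'s file output; every table is read with
#' the package's validating readers.
#'
#' @param dir Directory written by [simulate_dataset()].
#' @return A bundle list as returned by [simulate_dataset()].
#' @export
read_dataset <- function(dir) {
  parse_list <- function(x, mode) {
    x[is.na(x)] <- ""
    lapply(strsplit(x, ",", fixed = TRUE), function(v) {
      v <- v[nzchar(v)]
      if (mode == "integer") as.integer(v) else v
    })
  }
  reads <- readr::read_tsv(file.path(dir, "reads.tsv"),
                           col_types = readr::cols(
                             snp_pos = "c", snp_obs = "c",
                             .default = readr::col_guess()),
                           progress = FALSE)
  reads$snp_pos <- parse_list(as.character(reads$snp_pos), "integer")
  reads$snp_obs <- parse_list(as.character(reads$snp_obs), "character")
  list(
    truth = readr::read_tsv(file.path(dir, "truth.tsv"),
                            progress = FALSE, show_col_types = FALSE),
    dhs = read_counts(file.path(dir, "dhs_counts.tsv")),
    expression = read_counts(file.path(dir, "expression_counts.tsv")),
    reads = reads,
    snps = read_snp_table(file.path(dir, "snps.tsv")),
    methylomes = list(oocyte = read_methylation(file.path(dir, "meth_oocyte.tsv")),
                      sperm = read_methylation(file.path(dir, "meth_sperm.tsv"))),
    chip = readr::read_tsv(file.path(dir, "chip.tsv"),
                           progress = FALSE, show_col_types = FALSE),
    genes = read_genes(file.path(dir, "genes.tsv"))
  )
}

#' Convert long allelic DHS counts to per-replicate RPKMs
#'
#' Library size is the per-sample (condition x allele x replicate) total
#' over the DHS catalogue.
#'
#' @param dhs Long tibble from [generate_dhs_counts()] (or the same
#'   schema): `locus_id`, `chrom`, `start`, `end`, `condition`, `allele`,
#'   `replicate`, `count`.
#' @return The tibble with an `rpkm` column.
#' @export
quantify_rpkm <- function(dhs) {
  dhs |>
    dplyr::group_by(.data$condition, .data$allele, .data$replicate) |>
    dplyr::mutate(rpkm = rpkm(.data$count, .data$end - .data$start,
                              sum(.data$count))) |>
    dplyr::ungroup()
}

#' Randomly permute maternal/paternal labels of a ChIP table
#'
#' Sanity-null helper: swaps `mat_rpm` and `pat_rpm` for a random half of
#' the rows. Running the cascade on a permuted table should collapse
#' candidate recall to the background rate.
#'
#' @param chip Tibble with `mat_rpm`, `pat_rpm`.
#' @param seed Seed for the swap draw.
#' @return The permuted tibble.
#' @export
permute_chip_alleles <- function(chip, seed = 1L) {
  swap <- withr::with_seed(seed, stats::runif(nrow(chip)) < 0.5)
  out <- chip
  out$mat_rpm[swap] <- chip$pat_rpm[swap]
  out$pat_rpm[swap] <- chip$mat_rpm[swap]
  out
}

#' Run the full discovery pipeline on a data bundle
#'
#' End-to-end composition: SNP read splitting (filter, assign, count),
#' morula AG/GG accessibility quantification and allelic DHS
#' classification, oocyte methylation classes, allelic H3K27me3 bias at
#' ICM and zygote, the candidate cascade, morula AG/GG expression bias of
#' the candidates (ERCC-normalised FPKM), and — when the Kdm6b arms are
#' present — rescue classification of reliable paternal-specific DHSs and
#' candidate-gene derepression tests. The manifest records the seed-bearing
#' inputs, thresholds used and per-stage row counts.
#'
#' @param bundle A bundle from [simulate_dataset()] / [read_dataset()], or
#'   a directory path containing one.
#' @param config A [pipeline_config()].
#' @return An object of class `imprintscan_run`: list with `dhs_calls`,
#'   `meth`, `cascade`, `candidates`, `expression_bias`, `rescue`,
#'   `derepression`, `allelic_counts`, `manifest`.
#' @export
run_pipeline <- function(bundle, config = pipeline_config()) {
  if (is.character(bundle)) bundle <- read_dataset(bundle)
  stopifnot(inherits(config, "pipeline_config"))

  # -- allele splitting of SNP-bearing reads over the locus catalogue
  filtered <- filter_reads(bundle$reads,
                           mapq_max_removed = config$mapq_max_removed)
  assignments <- assign_alleles(filtered, bundle$snps,
                                cross_direction = config$cross_direction)
  loci <- dplyr::distinct(bundle$truth[, c("locus_id", "chrom", "start",
                                           "end", "sex_chrom")])
  allelic_counts <- count_allelic(assignments, filtered, loci)

  # -- morula allelic accessibility: GG reads out the maternal genome,
  #    AG the paternal
  morula <- quantify_rpkm(
    bundle$dhs[bundle$dhs$condition %in% c("AG_morula", "GG_morula"), ])
  dhs_calls <- classify_allelic_dhs(
    dplyr::mutate(morula,
                  sex_chrom = .data$chrom %in% config$sex_chroms),
    mean_min = config$dhs_mean_min, rep_min = config$dhs_rep_min,
    fc_min = config$dhs_fc_min)

  # -- oocyte methylation class at each DHS
  meth <- interval_methylation(bundle$methylomes$oocyte, loci) |>
    dplyr::mutate(meth_class = methylation_class(
      .data$meth_mean, hypo_max = config$meth_hypo_max,
      hyper_min = config$meth_hyper_min))

  # -- cascade
  chip_icm <- bundle$chip[bundle$chip$stage == "icm", ]
  chip_zyg <- bundle$chip[bundle$chip$stage == "zygote", ]
  cascade <- run_cascade(dhs_calls, meth, chip_icm, chip_zyg, bundle$genes,
                         rpm_min = config$chip_rpm_min)

  # -- candidate expression bias in AG vs GG morulae
  morula_expr <- bundle$expression[
    bundle$expression$stage %in% c("morula_AG", "morula_GG"), ]
  sf <- size_factors_ercc(morula_expr)
  fp <- fpkm(morula_expr[!morula_expr$is_ercc, ], sf)
  expression_bias <- fp |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      ag_fpkm = mean(.data$fpkm[.data$stage == "morula_AG"]),
      gg_fpkm = mean(.data$fpkm[.data$stage == "morula_GG"]),
      .groups = "drop") |>
    dplyr::mutate(
      bias = morula_bias(.data$ag_fpkm, .data$gg_fpkm,
                         expressed_min = config$expressed_min,
                         fc_biased = config$bias_fc,
                         fc_high = config$high_bias_fc),
      candidate = .data$gene_id %in% cascade$candidates$gene_id)

  # -- Kdm6b arms: rescue of reliable Ps-DHSs, derepression of candidates
  rescue <- NULL
  kdm6b_dhs <- bundle$dhs[bundle$dhs$condition %in%
                            c("PG_kdm6b_wt", "PG_kdm6b_mut"), ]
  if (nrow(kdm6b_dhs) > 0) {
    # PG embryos read out the maternal genome; AG morulae supply the
    # paternal reference in both arms
    ag <- dplyr::mutate(
      morula[morula$condition == "AG_morula", ], arm = "both")
    kd <- quantify_rpkm(kdm6b_dhs) |>
      dplyr::mutate(arm = dplyr::if_else(.data$condition == "PG_kdm6b_wt",
                                         "wt", "mut"))
    quant <- dplyr::bind_rows(
      kd,
      dplyr::mutate(ag, arm = "wt"),
      dplyr::mutate(ag, arm = "mut"))
    ps <- dhs_calls$locus_id[dhs_calls$class == "paternal-specific"]
    rescue <- classify_rescue(
      quant[quant$locus_id %in% ps, ],
      wt_mat_min = config$rescue_wt_mat_min,
      wt_fc_max = config$rescue_wt_fc_max,
      mean_min = config$dhs_mean_min, rep_min = config$dhs_rep_min,
      fc_min = config$dhs_fc_min)
  }
  derepression <- NULL
  kdm6b_expr <- bundle$expression[
    bundle$expression$stage %in% c("morula_PG_kdm6b_wt",
                                   "morula_PG_kdm6b_mut"), ]
  if (nrow(kdm6b_expr) > 0 && nrow(cascade$candidates) > 0) {
    sf_k <- size_factors_ercc(kdm6b_expr)
    derepression <- derepression_test(
      kdm6b_expr[!kdm6b_expr$is_ercc, ],
      wt_samples = unique(kdm6b_expr$sample[
        kdm6b_expr$stage == "morula_PG_kdm6b_wt"]),
      mut_samples = unique(kdm6b_expr$sample[
        kdm6b_expr$stage == "morula_PG_kdm6b_mut"]),
      size_factors = sf_k,
      candidate_genes = cascade$candidates$gene_id,
      fdr_max = config$nascent_fdr)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("imprintscan")),
    thresholds = unclass(config),
    n_reads_in = nrow(bundle$reads),
    n_reads_filtered = nrow(filtered),
    n_loci = nrow(loci),
    cascade_survivors = cascade$counts,
    n_candidates = nrow(cascade$candidates)
  )
  structure(
    list(dhs_calls = dhs_calls, meth = meth, cascade = cascade,
         candidates = cascade$candidates,
         expression_bias = expression_bias, rescue = rescue,
         derepression = derepression, allelic_counts = allelic_counts,
         manifest = manifest),
    class = "imprintscan_run"
  )
}

#' @export
print.imprintscan_run <- function(x, ...) {
  cat("imprintscan pipeline run\n")
  cat(sprintf("  loci: %d   reads kept: %d/%d\n", x$manifest$n_loci,
              x$manifest$n_reads_filtered, x$manifest$n_reads_in))
  print(x$cascade)
  biased <- sum(x$expression_bias$candidate &
                  x$expression_bias$bias %in% c("biased", "highly biased"))
  cat(sprintf("  candidate genes with biased AG/GG expression: %d\n", biased))
  invisible(x)
}
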