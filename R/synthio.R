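#' Configuration for the synthetic multi-omic generator
#'
#' Builds the parameter set used by every `generate_*()` function. The
#' generator emulates the study design used to discover H3K27me3-dependent
#' imprinting: allele-resolved DNase I hypersensitivity in zygotes and
#' uniparental (AG/GG) morulae, 2-cell transcriptomes with a maternal
#' stored-transcript pool, ERCC spike-ins and alpha-amanitin controls,
#' bimodal gamete DNA methylomes, maternal-biased H3K27me3 domains,
#' SNP-bearing reads from a hybrid cross, and a Kdm6b (H3K27me3 demethylase)
#' injection arm with a catalytic-mutant control.
#'
#' Loci come in three planted classes. `none`: accessible and expressed from
#' both alleles. `canonical`: a germline-DMR-like locus — oocyte
#' hypermethylated, sperm hypomethylated, low maternal H3K27me3, maternal
#' allele closed, paternally expressed. `non-canonical`: oocyte
#' hypomethylated but carrying a strong maternal H3K27me3 domain, maternal
#' allele closed, paternally expressed; this is the class the discovery
#' cascade is designed to recover.
#'
#' @param n_autosomal_loci Number of autosomal loci.
#' @param n_sex_loci Number of sex-chromosome (chrX) loci; these are always
#'   planted as class `none` and are excluded by the accessibility caller.
#' @param frac_canonical,frac_noncanonical Fractions of autosomal loci in
#'   the two imprinted classes; the remainder is bi-allelic background.
#' @param n_replicates Replicates per condition/sample type.
#' @param mean_depth Expected reads at an open locus allele (also the
#'   expected nascent count of an expressed gene).
#' @param nb_dispersion NB dispersion alpha (variance = mu + alpha mu^2);
#'   0 gives the deterministic expected-count limit.
#' @param maternal_store_level Expected FPKM-scale level of maternally
#'   stored transcripts shared by all 2-cell samples.
#' @param ercc_n Number of ERCC spike-in species.
#' @param snp_density Strain SNPs per kb inside locus regions.
#' @param error_rate Per-SNP base-observation error rate for simulated reads.
#' @param kdm6b_efficiency Fraction of non-canonical loci whose maternal
#'   H3K27me3 is erased in the Kdm6b-WT arm (per-locus Bernoulli).
#' @param meth_noise Per-CpG sd of methylation noise (beta); 0 is exact.
#' @param chip_cv Coefficient of variation of allelic ChIP RPM (gamma);
#'   0 is exact.
#' @param size_factor_sd sd of log-normal per-sample true size factors for
#'   expression libraries; 0 fixes all true factors at 1.
#' @param background_frac Closed-allele accessibility background, as a
#'   fraction of `mean_depth`.
#' @param locus_width Width (bp) of each DHS interval.
#' @param read_length Simulated read length (bp).
#' @param seed Master seed; every emitted table draws from an independent,
#'   named substream derived from it.
#'
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_autosomal_loci = 200,
                             n_sex_loci = 10,
                             frac_canonical = 0.1,
                             frac_noncanonical = 0.1,
                             n_replicates = 3,
                             mean_depth = 200,
                             nb_dispersion = 0.05,
                             maternal_store_level = 20,
                             ercc_n = 50,
                             snp_density = 5,
                             error_rate = 0,
                             kdm6b_efficiency = 0.9,
                             meth_noise = 0.05,
                             chip_cv = 0.2,
                             size_factor_sd = 0.3,
                             background_frac = 0.02,
                             locus_width = 600,
                             read_length = 50,
                             seed = 1L) {
  stopifnot_count(n_autosomal_loci, "n_autosomal_loci")
  stopifnot_count(n_sex_loci, "n_sex_loci", min = 0)
  stopifnot_count(n_replicates, "n_replicates")
  stopifnot_scalar_fraction(frac_canonical, "frac_canonical")
  stopifnot_scalar_fraction(frac_noncanonical, "frac_noncanonical")
  stopifnot_scalar_fraction(kdm6b_efficiency, "kdm6b_efficiency")
  stopifnot_scalar_fraction(error_rate, "error_rate")
  if (frac_canonical + frac_noncanonical > 1) {
    stop("frac_canonical + frac_noncanonical must be <= 1", call. = FALSE)
  }
  if (mean_depth <= 0 || nb_dispersion < 0 || snp_density < 0 ||
      meth_noise < 0 || chip_cv < 0 || size_factor_sd < 0) {
    stop("noise and depth parameters must be non-negative (depth > 0)",
         call. = FALSE)
  }
  stopifnot_count(ercc_n, "ercc_n")
  structure(
    list(
      n_autosomal_loci = as.integer(n_autosomal_loci),
      n_sex_loci = as.integer(n_sex_loci),
      frac_canonical = frac_canonical,
      frac_noncanonical = frac_noncanonical,
      frac_biallelic = 1 - frac_canonical - frac_noncanonical,
      n_replicates = as.integer(n_replicates),
      mean_depth = mean_depth,
      nb_dispersion = nb_dispersion,
      maternal_store_level = maternal_store_level,
      ercc_n = as.integer(ercc_n),
      snp_density = snp_density,
      error_rate = error_rate,
      kdm6b_efficiency = kdm6b_efficiency,
      meth_noise = meth_noise,
      chip_cv = chip_cv,
      size_factor_sd = size_factor_sd,
      background_frac = background_frac,
      locus_width = as.integer(locus_width),
      read_length = as.integer(read_length),
      autosomes = paste0("chr", 1:5),
      sex_chroms = c("chrX", "chrY"),
      locus_spacing = 10000L,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

dhs_conditions <- c("zygote_matPN", "zygote_patPN", "AG_morula", "GG_morula",
                    "PG_kdm6b_wt", "PG_kdm6b_mut")

# Which parental allele each accessibility library reads out. AG embryos
# carry two paternal genomes, GG/PG two maternal genomes.
condition_allele <- c(
  zygote_matPN = "maternal", zygote_patPN = "paternal",
  AG_morula = "paternal", GG_morula = "maternal",
  PG_kdm6b_wt = "maternal", PG_kdm6b_mut = "maternal"
)

#' Generate planted locus-level ground truth
#'
#' Lays out uniformly spaced loci on a small synthetic genome (five 2-Mb
#' autosomes plus chrX), assigns each a gene whose TSS sits inside the
#' locus interval, and plants the imprint class with its methylation,
#' H3K27me3, accessibility and expression consequences.
#'
#' @param config A [generator_config()].
#' @return A tibble with one row per locus: `locus_id`, `chrom`, `start`,
#'   `end`, `sex_chrom`, `gene_id`, `tss`, `strand`, `exonic_length`,
#'   `imprint_class`, `oocyte_meth`, `sperm_meth`, `mat_k27_rpm`,
#'   `pat_k27_rpm`, `mat_open`, `pat_open`, `expressed_allele`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n_auto <- config$n_autosomal_loci
  n_sex <- config$n_sex_loci
  n <- n_auto + n_sex

  chrom <- c(config$autosomes[((seq_len(n_auto) - 1) %% length(config$autosomes)) + 1],
             rep(config$sex_chroms[1], n_sex))
  idx_on_chrom <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  start <- 50000L + (as.integer(idx_on_chrom) - 1L) * config$locus_spacing
  end <- start + config$locus_width

  n_canon <- round(config$frac_canonical * n_auto)
  n_noncanon <- round(config$frac_noncanonical * n_auto)
  class_pool <- c(rep("canonical", n_canon), rep("non-canonical", n_noncanon),
                  rep("none", n_auto - n_canon - n_noncanon))
  imprint_class <- with_substream(config$seed, "truth/classes", {
    c(sample(class_pool), rep("none", n_sex))
  })

  truth <- tibble::tibble(
    locus_id = sprintf("L%04d", seq_len(n)),
    chrom = chrom,
    start = start,
    end = end,
    sex_chrom = chrom %in% config$sex_chroms,
    gene_id = sprintf("G%04d", seq_len(n)),
    tss = start + config$locus_width %/% 2L,
    strand = "+",
    imprint_class = imprint_class
  )
  truth$exonic_length <- with_substream(config$seed, "truth/lengths", {
    round(stats::rlnorm(n, meanlog = log(1500), sdlog = 0.4))
  })

  planted <- list(
    none = list(oo = 0.10, sp = 0.10, mk = 0.10, pk = 0.10,
                mo = TRUE, po = TRUE, ex = "both"),
    canonical = list(oo = 0.90, sp = 0.05, mk = 0.10, pk = 0.10,
                     mo = FALSE, po = TRUE, ex = "paternal"),
    `non-canonical` = list(oo = 0.05, sp = 0.05, mk = 2.0, pk = 0.10,
                           mo = FALSE, po = TRUE, ex = "paternal")
  )
  pick <- function(field, mode) {
    unname(vapply(truth$imprint_class, function(cl) planted[[cl]][[field]],
                  mode))
  }
  truth$oocyte_meth <- pick("oo", numeric(1))
  truth$sperm_meth <- pick("sp", numeric(1))
  truth$mat_k27_rpm <- pick("mk", numeric(1))
  truth$pat_k27_rpm <- pick("pk", numeric(1))
  truth$mat_open <- pick("mo", logical(1))
  truth$pat_open <- pick("po", logical(1))
  truth$expressed_allele <- pick("ex", character(1))
  truth
}

# Per-locus Bernoulli draw of Kdm6b-mediated maternal H3K27me3 erasure.
# Shared (same substream) by the accessibility, expression and ChIP arms so
# the perturbation is consistent across assays.
kdm6b_rescued <- function(truth, config) {
  p <- with_substream(config$seed, "kdm6b/rescue",
                      stats::runif(nrow(truth)))
  truth$imprint_class == "non-canonical" & p < config$kdm6b_efficiency
}

#' Generate allelic DNase accessibility counts for one condition
#'
#' Draws per-replicate NB read counts at each locus for one library type.
#' Open alleles draw around `mean_depth`, closed alleles around the low
#' background `background_frac * mean_depth`. The two Kdm6b injection arms
#' share a base random substream, so with `kdm6b_efficiency = 0` the WT arm
#' is count-identical to the mutant arm, and canonical (DNA-methylation
#' protected) loci are identical between arms under any efficiency.
#'
#' @param truth Output of [generate_truth()].
#' @param config The matching [generator_config()].
#' @param condition One of `"zygote_matPN"`, `"zygote_patPN"`,
#'   `"AG_morula"`, `"GG_morula"`, `"PG_kdm6b_wt"`, `"PG_kdm6b_mut"`.
#' @return A tibble `locus_id`, `chrom`, `start`, `end`, `sex_chrom`,
#'   `condition`, `allele`, `replicate`, `count`.
#' @export
generate_dhs_counts <- function(truth, config, condition) {
  stopifnot(inherits(config, "generator_config"))
  if (!condition %in% dhs_conditions) {
    stop(sprintf("unknown condition '%s'", condition), call. = FALSE)
  }
  allele <- condition_allele[[condition]]
  open <- if (allele == "maternal") truth$mat_open else truth$pat_open

  # Kdm6b arms: identical base stream; WT re-opens rescued maternal alleles.
  stream_cond <- if (condition %in% c("PG_kdm6b_wt", "PG_kdm6b_mut")) {
    "PG_kdm6b"
  } else {
    condition
  }
  mu_open <- config$mean_depth
  mu_closed <- config$background_frac * config$mean_depth
  nrep <- config$n_replicates

  counts <- lapply(seq_len(nrow(truth)), function(i) {
    mu <- if (open[i]) mu_open else mu_closed
    with_substream(config$seed, paste("dhs", stream_cond, truth$locus_id[i]),
                   rnb(nrep, mu, config$nb_dispersion))
  })
  if (condition == "PG_kdm6b_wt") {
    resc <- kdm6b_rescued(truth, config)
    for (i in which(resc & !open)) {
      counts[[i]] <- with_substream(
        config$seed, paste("dhs/kdm6b_open", truth$locus_id[i]),
        rnb(nrep, mu_open, config$nb_dispersion))
    }
  }

  tibble::tibble(
    locus_id = rep(truth$locus_id, each = nrep),
    chrom = rep(truth$chrom, each = nrep),
    start = rep(truth$start, each = nrep),
    end = rep(truth$end, each = nrep),
    sex_chrom = rep(truth$sex_chrom, each = nrep),
    condition = condition,
    allele = allele,
    replicate = rep(paste0("rep", seq_len(nrep)), times = nrow(truth)),
    count = unlist(counts)
  )
}

expression_stages <- c("two_cell_AG", "two_cell_GG", "two_cell_Ama",
                       "morula_AG", "morula_GG",
                       "morula_PG_kdm6b_wt", "morula_PG_kdm6b_mut")

# Does this sample type transcribe the gene, given its expressed allele and
# (for the Kdm6b arms) whether the locus was rescued?
stage_expresses <- function(stage, expressed_allele, rescued) {
  genome <- switch(stage,
    two_cell_AG = , morula_AG = "paternal",
    two_cell_GG = , morula_GG = "maternal",
    two_cell_Ama = "none",
    morula_PG_kdm6b_wt = , morula_PG_kdm6b_mut = "maternal"
  )
  if (genome == "none") return(rep(FALSE, length(expressed_allele)))
  base <- expressed_allele == "both" | expressed_allele == genome
  if (stage == "morula_PG_kdm6b_wt") base | rescued else base
}

#' Generate an expression count table for one sample type
#'
#' Every 2-cell sample contains the same expected maternal stored-transcript
#' component (gene-specific log-normal means shared across AG, GG and
#' alpha-amanitin samples); nascent transcription is added only where the
#' sample's genome carries an expressed allele; alpha-amanitin samples
#' contain the store alone. ERCC spike-in rows scale with a per-sample true
#' size factor recorded in the `true_size_factors` attribute (and in the
#' `true_size_factor` column). Morula samples contain nascent transcription
#' only; the Kdm6b-WT parthenogenote arm additionally expresses rescued
#' non-canonical genes.
#'
#' @inheritParams generate_dhs_counts
#' @param stage One of `"two_cell_AG"`, `"two_cell_GG"`, `"two_cell_Ama"`,
#'   `"morula_AG"`, `"morula_GG"`, `"morula_PG_kdm6b_wt"`,
#'   `"morula_PG_kdm6b_mut"`.
#' @return A long tibble `gene_id`, `stage`, `sample`, `replicate`,
#'   `is_ercc`, `exonic_length`, `true_size_factor`, `count`, with the named
#'   vector of true size factors as attribute `true_size_factors`.
#' @export
generate_expression <- function(truth, config, stage) {
  stopifnot(inherits(config, "generator_config"))
  if (!stage %in% expression_stages) {
    stop(sprintf("unknown stage '%s'", stage), call. = FALSE)
  }
  nrep <- config$n_replicates
  samples <- paste0(stage, "_rep", seq_len(nrep))
  two_cell <- grepl("^two_cell", stage)

  store_mean <- with_substream(config$seed, "expr/store", {
    config$maternal_store_level * stats::rlnorm(nrow(truth), 0, 1)
  })
  rescued <- kdm6b_rescued(truth, config)
  expressed <- stage_expresses(stage, truth$expressed_allele, rescued)

  # Expected counts per gene: shared store (2-cell only, converted to count
  # scale via exonic length) + nascent component on expressing genomes.
  store_counts <- if (two_cell) store_mean * truth$exonic_length / 1000 else 0
  nascent <- ifelse(expressed, config$mean_depth, 0)
  gene_mu <- store_counts + nascent

  sf <- with_substream(config$seed, paste("expr/sf", stage), {
    if (config$size_factor_sd <= 0) rep(1, nrep)
    else stats::rlnorm(nrep, 0, config$size_factor_sd)
  })
  names(sf) <- samples

  ercc_mean <- 2^seq(2, 12, length.out = config$ercc_n)
  ercc_ids <- sprintf("ERCC-%05d", seq_len(config$ercc_n))

  per_sample <- lapply(seq_len(nrep), function(j) {
    gene_counts <- with_substream(
      config$seed, paste("expr", stage, "genes", j),
      rnb(length(gene_mu), gene_mu * sf[j], config$nb_dispersion))
    ercc_counts <- with_substream(
      config$seed, paste("expr", stage, "ercc", j),
      rnb(length(ercc_mean), ercc_mean * sf[j], config$nb_dispersion))
    tibble::tibble(
      gene_id = c(truth$gene_id, ercc_ids),
      stage = stage,
      sample = samples[j],
      replicate = paste0("rep", j),
      is_ercc = c(rep(FALSE, nrow(truth)), rep(TRUE, config$ercc_n)),
      exonic_length = c(truth$exonic_length, rep(1000, config$ercc_n)),
      true_size_factor = sf[j],
      count = c(gene_counts, ercc_counts)
    )
  })
  out <- dplyr::bind_rows(per_sample)
  attr(out, "true_size_factors") <- sf
  out
}

#' Generate SNP-bearing reads from the two parental haplotypes
#'
#' Plants strain SNPs at `snp_density` per kb inside each locus region
#' (extended by one read length), then emits ungapped reads from each
#' parental haplotype with the haplotype's base observed at every covered
#' SNP (flipped with probability `error_rate`). The true parental origin of
#' every read is recorded, as is per-read SNP coverage geometry, so
#' assignment accuracy is checkable exactly.
#'
#' @inheritParams generate_dhs_counts
#' @return A list with `reads` (tibble: `read_id`, `chrom`, `start`, `end`,
#'   `orientation`, `mapq`, `origin`, `snp_pos` and `snp_obs` list-columns)
#'   and `snps` (tibble: `chrom`, `pos`, `mat_base`, `pat_base`).
#' @export
generate_reads <- function(truth, config) {
  stopifnot(inherits(config, "generator_config"))
  bases <- c("A", "C", "G", "T")
  rl <- config$read_length

  snps <- with_substream(config$seed, "reads/snps", {
    per_locus <- lapply(seq_len(nrow(truth)), function(i) {
      lo <- max(0L, truth$start[i] - rl)
      hi <- truth$end[i] + rl
      n_snp <- round((hi - lo) / 1000 * config$snp_density)
      if (n_snp == 0) return(NULL)
      pos <- sort(sample(seq.int(lo, hi - 1L), n_snp))
      mat <- sample(bases, n_snp, replace = TRUE)
      pat <- vapply(mat, function(b) sample(setdiff(bases, b), 1), character(1))
      tibble::tibble(chrom = truth$chrom[i], pos = pos,
                     mat_base = mat, pat_base = unname(pat))
    })
    empty <- tibble::tibble(chrom = character(), pos = integer(),
                            mat_base = character(), pat_base = character())
    dplyr::distinct(dplyr::bind_rows(c(list(empty), per_locus)),
                    .data$chrom, .data$pos, .keep_all = TRUE)
  })

  n_per_allele <- max(1L, round(config$mean_depth / 2))
  reads <- with_substream(config$seed, "reads/records", {
    recs <- lapply(seq_len(nrow(truth)), function(i) {
      loc_snps <- snps[snps$chrom == truth$chrom[i] &
                         snps$pos >= max(0L, truth$start[i] - rl) &
                         snps$pos < truth$end[i] + rl, ]
      lapply(c("maternal", "paternal"), function(origin) {
        start <- sample(seq.int(max(0L, truth$start[i] - rl %/% 2),
                                truth$end[i] - rl %/% 2),
                        n_per_allele, replace = TRUE)
        hap <- if (origin == "maternal") loc_snps$mat_base else loc_snps$pat_base
        covered <- lapply(start, function(s) {
          which(loc_snps$pos >= s & loc_snps$pos < s + rl)
        })
        obs <- lapply(covered, function(ix) {
          b <- hap[ix]
          if (config$error_rate > 0 && length(b) > 0) {
            flip <- stats::runif(length(b)) < config$error_rate
            b[flip] <- vapply(b[flip], function(x) sample(setdiff(bases, x), 1),
                              character(1))
          }
          b
        })
        tibble::tibble(
          chrom = truth$chrom[i],
          start = start,
          end = start + rl,
          orientation = sample(c("+", "-"), n_per_allele, replace = TRUE),
          mapq = 42L,
          origin = origin,
          snp_pos = lapply(covered, function(ix) loc_snps$pos[ix]),
          snp_obs = obs
        )
      })
    })
    dplyr::bind_rows(unlist(recs, recursive = FALSE))
  })
  reads$read_id <- sprintf("R%06d", seq_len(nrow(reads)))
  reads <- reads[, c("read_id", "chrom", "start", "end", "orientation",
                     "mapq", "origin", "snp_pos", "snp_obs")]
  list(reads = reads, snps = snps)
}

#' Generate oocyte and sperm per-CpG methylomes
#'
#' Emits CpG records tiling each locus interval extended by 2 kb on each
#' side, with per-CpG methylation fractions drawn (beta noise) around the
#' planted class means: canonical loci are oocyte-hypermethylated /
#' sperm-hypomethylated, non-canonical and background loci hypomethylated
#' in both gametes.
#'
#' @inheritParams generate_dhs_counts
#' @param cpg_spacing Spacing (bp) between simulated CpGs.
#' @return A list of two bedGraph-like tibbles, `oocyte` and `sperm`, with
#'   columns `chrom`, `start`, `end`, `level`, `coverage`.
#' @export
generate_methylomes <- function(truth, config, cpg_spacing = 100L) {
  stopifnot(inherits(config, "generator_config"))
  one_tissue <- function(tissue, planted) {
    with_substream(config$seed, paste("meth", tissue), {
      per_locus <- lapply(seq_len(nrow(truth)), function(i) {
        pos <- seq.int(max(0L, truth$start[i] - 2000L),
                       truth$end[i] + 2000L - 1L, by = cpg_spacing)
        tibble::tibble(
          chrom = truth$chrom[i],
          start = pos,
          end = pos + 2L,
          level = rbeta_ms(length(pos), planted[i], config$meth_noise),
          coverage = stats::rpois(length(pos), 20) + 1L
        )
      })
      dplyr::bind_rows(per_locus)
    })
  }
  list(oocyte = one_tissue("oocyte", truth$oocyte_meth),
       sperm = one_tissue("sperm", truth$sperm_meth))
}

#' Generate an allelic H3K27me3 signal table
#'
#' Draws maternal and paternal RPM (gamma noise) around the planted
#' H3K27me3 means for each locus at one stage. In the Kdm6b-WT arm the
#' maternal signal of rescued non-canonical loci is multiplied by
#' `1 - kdm6b_efficiency` (shared rescue draw with the accessibility and
#' expression arms); the mutant arm is untouched.
#'
#' @inheritParams generate_dhs_counts
#' @param stage One of `"gamete"`, `"zygote"`, `"icm"`.
#' @param kdm6b `"none"` (default), `"wt"` or `"mut"`.
#' @return A tibble `locus_id`, `chrom`, `start`, `end`, `stage`,
#'   `mat_rpm`, `pat_rpm`.
#' @export
generate_chip <- function(truth, config, stage = c("gamete", "zygote", "icm"),
                          kdm6b = c("none", "wt", "mut")) {
  stopifnot(inherits(config, "generator_config"))
  stage <- match.arg(stage)
  kdm6b <- match.arg(kdm6b)
  mat_mean <- truth$mat_k27_rpm
  if (kdm6b == "wt") {
    resc <- kdm6b_rescued(truth, config)
    mat_mean[resc] <- mat_mean[resc] * (1 - config$kdm6b_efficiency)
  }
  with_substream(config$seed, paste("chip", stage, kdm6b), {
    tibble::tibble(
      locus_id = truth$locus_id,
      chrom = truth$chrom,
      start = truth$start,
      end = truth$end,
      stage = stage,
      mat_rpm = rgamma_cv(nrow(truth), mat_mean, config$chip_cv),
      pat_rpm = rgamma_cv(nrow(truth), truth$pat_k27_rpm, config$chip_cv)
    )
  })
}
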