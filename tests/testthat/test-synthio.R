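test_that("truth generation is deterministic and respects class fractions", {
  cfg <- small_config()
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_identical(t1, t2)

  # degenerate fractions: everything bi-allelic background
  t0 <- generate_truth(small_config(frac_canonical = 0, frac_noncanonical = 0))
  expect_true(all(t0$imprint_class == "none"))

  # large run: realised non-canonical fraction within 2% of requested
  big <- generator_config(n_autosomal_loci = 1000, n_sex_loci = 0,
                          frac_noncanonical = 0.1, frac_canonical = 0.1,
                          seed = 7L)
  tb <- generate_truth(big)
  expect_lt(abs(mean(tb$imprint_class == "non-canonical") - 0.1), 0.02)

  # every gene TSS sits inside its locus; sex loci labelled
  expect_true(all(t1$tss >= t1$start & t1$tss < t1$end))
  expect_true(all(t1$sex_chrom == (t1$chrom %in% c("chrX", "chrY"))))
  expect_error(generator_config(frac_canonical = 0.7, frac_noncanonical = 0.4),
               "must be <= 1")
})

test_that("planted truth honours the two imprinting mechanisms", {
  tr <- generate_truth(small_config())
  canon <- tr[tr$imprint_class == "canonical", ]
  noncanon <- tr[tr$imprint_class == "non-canonical", ]
  expect_true(all(canon$oocyte_meth > 0.8 & canon$sperm_meth < 0.2))
  expect_true(all(canon$mat_k27_rpm <= canon$pat_k27_rpm))
  expect_true(all(noncanon$oocyte_meth < 0.2))
  expect_true(all(noncanon$mat_k27_rpm > 4 * noncanon$pat_k27_rpm))
  expect_true(all(!canon$mat_open & canon$pat_open))
  expect_true(all(noncanon$expressed_allele == "paternal"))
})

test_that("DHS counts follow the configured NB moments", {
  cfg <- generator_config(n_autosomal_loci = 20, n_sex_loci = 0,
                          n_replicates = 50, mean_depth = 200,
                          nb_dispersion = 0.05, frac_canonical = 0,
                          frac_noncanonical = 0, seed = 5L)
  tr <- generate_truth(cfg)
  d <- generate_dhs_counts(tr, cfg, "zygote_patPN")
  per_locus <- split(d$count, d$locus_id)
  mu <- 200
  se_mean <- sqrt(mu + 0.05 * mu^2) / sqrt(50)
  ok_mean <- vapply(per_locus, function(x) abs(mean(x) - mu) < 3 * se_mean,
                    logical(1))
  # 3-SE moment check per locus; allow rare misses across 20 loci
  expect_gt(mean(ok_mean), 0.9)
  # pooled variance consistent with mu + alpha mu^2
  v <- mean(vapply(per_locus, stats::var, numeric(1)))
  expect_lt(abs(v - (mu + 0.05 * mu^2)) / (mu + 0.05 * mu^2), 0.25)

  # near-zero dispersion: replicate counts concentrate at the mean
  cfg0 <- generator_config(n_autosomal_loci = 5, n_sex_loci = 0,
                           n_replicates = 50, mean_depth = 200,
                           nb_dispersion = 1e-6, frac_canonical = 0,
                           frac_noncanonical = 0, seed = 5L)
  d0 <- generate_dhs_counts(generate_truth(cfg0), cfg0, "zygote_patPN")
  expect_lt(abs(mean(d0$count) - 200), 3 * sqrt(200 / 50))
})

test_that("unknown condition and stage labels are rejected", {
  cfg <- small_config()
  tr <- generate_truth(cfg)
  expect_error(generate_dhs_counts(tr, cfg, "blastocyst"), "unknown condition")
  expect_error(generate_expression(tr, cfg, "four_cell"), "unknown stage")
})

test_that("Kdm6b perturbation is local to rescued non-canonical loci", {
  cfg <- small_config(kdm6b_efficiency = 1)
  tr <- generate_truth(cfg)
  wt <- generate_dhs_counts(tr, cfg, "PG_kdm6b_wt")
  mut <- generate_dhs_counts(tr, cfg, "PG_kdm6b_mut")
  cls <- tr$imprint_class[match(wt$locus_id, tr$locus_id)]
  # canonical and background loci: bit-identical counts between arms
  expect_identical(wt$count[cls != "non-canonical"],
                   mut$count[cls != "non-canonical"])
  # non-canonical maternal alleles re-open at full efficiency
  wt_nc <- tapply(wt$count[cls == "non-canonical"],
                  wt$locus_id[cls == "non-canonical"], mean)
  mut_nc <- tapply(mut$count[cls == "non-canonical"],
                   mut$locus_id[cls == "non-canonical"], mean)
  expect_true(all(wt_nc > 10 * mut_nc))

  # efficiency 0: the WT arm is count-identical to the mutant arm
  cfg0 <- small_config(kdm6b_efficiency = 0)
  tr0 <- generate_truth(cfg0)
  expect_identical(generate_dhs_counts(tr0, cfg0, "PG_kdm6b_wt")$count,
                   generate_dhs_counts(tr0, cfg0, "PG_kdm6b_mut")$count)
})

test_that("expression tables carry store, nascent and ERCC structure", {
  cfg <- small_config(nb_dispersion = 0, size_factor_sd = 0)
  tr <- generate_truth(cfg)
  ag <- generate_expression(tr, cfg, "two_cell_AG")
  gg <- generate_expression(tr, cfg, "two_cell_GG")
  ama <- generate_expression(tr, cfg, "two_cell_Ama")

  # with unit true factors and no count noise, ERCC rows are equal across
  # samples and across stages
  ercc_ag <- ag[ag$is_ercc, ]
  expect_true(all(tapply(ercc_ag$count, ercc_ag$gene_id,
                         function(x) length(unique(x))) == 1))
  expect_identical(ercc_ag$count, ama[ama$is_ercc, ]$count)

  # alpha-amanitin = maternal store only: no nascent component anywhere
  pat_genes <- tr$gene_id[tr$expressed_allele == "paternal"]
  ama_pat <- ama[ama$gene_id %in% pat_genes, ]
  ag_pat <- ag[ag$gene_id %in% pat_genes, ]
  gg_pat <- gg[gg$gene_id %in% pat_genes, ]
  # paternally expressed genes: AG = store + nascent, GG = Ama = store
  expect_identical(gg_pat$count, ama_pat$count)
  expect_true(all(ag_pat$count > ama_pat$count))

  # recorded true size factors match the attribute
  expect_equal(unique(ag$true_size_factor), 1)
  expect_equal(unname(attr(ag, "true_size_factors")), rep(1, cfg$n_replicates))
})

test_that("planted paternally expressed genes show AG over GG excess", {
  cfg <- small_config(nb_dispersion = 0.02, size_factor_sd = 0)
  tr <- generate_truth(cfg)
  ag <- generate_expression(tr, cfg, "morula_AG")
  gg <- generate_expression(tr, cfg, "morula_GG")
  pat_genes <- tr$gene_id[tr$expressed_allele == "paternal"]
  ag_mean <- tapply(ag$count[ag$gene_id %in% pat_genes],
                    ag$gene_id[ag$gene_id %in% pat_genes], mean)
  gg_mean <- tapply(gg$count[gg$gene_id %in% pat_genes],
                    gg$gene_id[gg$gene_id %in% pat_genes], mean)
  expect_true(all(ag_mean > 5 * (gg_mean + 1)))
})

test_that("reads carry haplotype-consistent bases and truth labels", {
  cfg <- small_config(error_rate = 0)
  tr <- generate_truth(cfg)
  rd <- generate_reads(tr, cfg)
  expect_true(all(rd$snps$mat_base != rd$snps$pat_base))
  expect_false(any(duplicated(paste(rd$snps$chrom, rd$snps$pos))))
  expect_setequal(unique(rd$reads$origin), c("maternal", "paternal"))
  # SNP positions attached to a read are inside the read
  i <- which(lengths(rd$reads$snp_pos) > 0)[1:50]
  for (j in i) {
    expect_true(all(rd$reads$snp_pos[[j]] >= rd$reads$start[j] &
                      rd$reads$snp_pos[[j]] < rd$reads$end[j]))
  }
  # zero SNP density leaves every read without observations
  cfg0 <- small_config(snp_density = 0)
  rd0 <- generate_reads(generate_truth(cfg0), cfg0)
  expect_equal(nrow(rd0$snps), 0)
  expect_true(all(lengths(rd0$reads$snp_pos) == 0))
})

test_that("methylomes reproduce planted class means", {
  cfg <- small_config(meth_noise = 0)
  tr <- generate_truth(cfg)
  m <- generate_methylomes(tr, cfg)
  im <- interval_methylation(m$oocyte, tr)
  # no noise: interval means equal the planted means exactly
  expect_equal(im$meth_mean, tr$oocyte_meth, tolerance = 1e-12)

  cfgn <- small_config()
  trn <- generate_truth(cfgn)
  mn <- generate_methylomes(trn, cfgn)
  imo <- interval_methylation(mn$oocyte, trn)
  ims <- interval_methylation(mn$sperm, trn)
  canon <- trn$imprint_class == "canonical"
  noncanon <- trn$imprint_class == "non-canonical"
  expect_true(all(imo$meth_mean[canon] > 0.8))
  expect_true(all(imo$meth_mean[noncanon] < 0.2))
  expect_true(all(ims$meth_mean[noncanon] < 0.2))
})

test_that("allelic ChIP signal satisfies stage criteria per class", {
  cfg <- small_config(chip_cv = 0)
  tr <- generate_truth(cfg)
  ch <- generate_chip(tr, cfg, "zygote")
  noncanon <- tr$imprint_class == "non-canonical"
  # noiseless: planted 2.0 vs 0.2-style means give the exact fold change
  expect_equal(ch$mat_rpm[noncanon] / ch$pat_rpm[noncanon],
               tr$mat_k27_rpm[noncanon] / tr$pat_k27_rpm[noncanon])

  cfgn <- small_config()
  trn <- generate_truth(cfgn)
  for (st in c("zygote", "icm")) {
    chn <- generate_chip(trn, cfgn, st)
    nc <- trn$imprint_class == "non-canonical"
    pass <- chip_allelic_bias(chn$mat_rpm, chn$pat_rpm, stage = st)
    expect_gte(mean(pass[nc]), 0.95)
    expect_lte(mean(pass[!nc]), 0.05)
  }

  # full erasure: no locus passes the maternal-bias criterion
  cfg1 <- small_config(kdm6b_efficiency = 1)
  tr1 <- generate_truth(cfg1)
  ch1 <- generate_chip(tr1, cfg1, "icm", kdm6b = "wt")
  expect_false(any(chip_allelic_bias(ch1$mat_rpm, ch1$pat_rpm, stage = "icm")))
})

test_that("identical config and seed give identical bundles", {
  cfg <- generator_config(n_autosomal_loci = 30, n_sex_loci = 2, seed = 9L)
  b1 <- simulate_dataset(cfg)
  b2 <- simulate_dataset(cfg)
  expect_identical(b1, b2)
})
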