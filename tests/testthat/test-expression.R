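long_counts <- function(m, genes = sprintf("g%02d", seq_len(nrow(m))),
                        samples = sprintf("s%d", seq_len(ncol(m))),
                        lengths = 1000) {
  tibble::tibble(gene_id = rep(genes, times = ncol(m)),
                 sample = rep(samples, each = nrow(m)),
                 count = as.vector(m),
                 exonic_length = rep_len(lengths, nrow(m) * ncol(m)))
}

test_that("ERCC size factors match the median-of-ratios closed form", {
  m <- withr::with_seed(2, matrix(rpois(40, 100), ncol = 2))
  m[, 2] <- 2 * m[, 1]  # pure scaling pair
  cnt <- long_counts(m, genes = sprintf("ERCC-%02d", 1:20))
  sf <- size_factors_ercc(cnt)
  expect_equal(sf$size_factor, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  ident <- long_counts(matrix(rep(c(5, 50, 500), 3), ncol = 3),
                       genes = sprintf("ERCC-%02d", 1:3))
  expect_equal(size_factors_ercc(ident)$size_factor, rep(1, 3))

  # independent cross-check against the reference median-of-ratios
  skip_if_not_installed("DESeq2")
  m2 <- withr::with_seed(3, matrix(rnbinom(60, mu = 80, size = 5) + 1, ncol = 3))
  cnt2 <- long_counts(m2, genes = sprintf("ERCC-%02d", 1:20))
  expect_equal(size_factors_ercc(cnt2)$size_factor,
               unname(DESeq2::estimateSizeFactorsForMatrix(m2)),
               tolerance = 1e-10)
})

test_that("size factors recover the generator's true factors", {
  cfg <- small_config(nb_dispersion = 0, size_factor_sd = 0.4, ercc_n = 60)
  tr <- generate_truth(cfg)
  e <- generate_expression(tr, cfg, "two_cell_AG")
  sf <- size_factors_ercc(e)
  truth <- attr(e, "true_size_factors")[sf$sample]
  ratio <- sf$size_factor / truth
  # proportional to truth within 1% (noise-free counts)
  expect_lt(max(ratio) / min(ratio) - 1, 0.01)
  expect_error(size_factors_ercc(long_counts(matrix(1:4, 2),
                                             genes = c("a", "b"))), "ERCC")
})

test_that("fpkm matches the long-hand formula and its invariances", {
  m <- matrix(c(100, 900000 - 100), ncol = 1)
  cnt <- long_counts(m, genes = c("g1", "g2"), lengths = c(1000, 899900))
  # 100 counts, 1 kb, 1e6-ish total: engineered so the total is exactly 1e6
  cnt$count <- c(100, 1e6 - 100)
  f <- fpkm(cnt)
  expect_equal(f$fpkm[f$gene_id == "g1"], 100)
  # doubling exon length halves FPKM
  cnt2 <- cnt
  cnt2$exonic_length[1] <- 2000
  expect_equal(fpkm(cnt2)$fpkm[1], f$fpkm[1] / 2)

  # random matrix against the definition applied long-hand
  m3 <- withr::with_seed(5, matrix(rpois(30, 50), ncol = 3))
  len <- withr::with_seed(6, sample(500:3000, 10))
  cnt3 <- long_counts(m3, lengths = rep(len, 3))
  sf3 <- tibble::tibble(sample = sprintf("s%d", 1:3),
                        size_factor = c(0.8, 1, 1.6))
  f3 <- fpkm(cnt3, sf3)
  normed <- sweep(m3, 2, sf3$size_factor, "/")
  common_total <- mean(colSums(normed))
  for (j in 1:3) {
    manual <- normed[, j] / (len / 1000) / (common_total / 1e6)
    expect_equal(f3$fpkm[f3$sample == sprintf("s%d", j)], manual)
  }
  # scaling one sample's counts scales its factor, FPKM unchanged
  cnt4 <- cnt3
  cnt4$count[cnt4$sample == "s1"] <- cnt4$count[cnt4$sample == "s1"] * 3
  sf4 <- sf3
  sf4$size_factor[1] <- sf4$size_factor[1] * 3
  expect_equal(fpkm(cnt4, sf4)$fpkm, f3$fpkm)
})

test_that("NB exact test matches its tail-sum oracle and conventions", {
  # frozen value computed with an independent enumeration of the
  # conditioned allocation distribution at dispersion 0.1
  expect_equal(nb_test(c(5, 6), c(50, 60), dispersion = 0.1),
               1.67444669084e-07, tolerance = 1e-9)
  # re-derive the oracle in place for a second case
  oracle_p <- function(a, b, alpha) {
    S <- sum(a) + sum(b)
    q0 <- S / (length(a) + length(b))
    muA <- q0 * length(a); muB <- q0 * length(b)
    szA <- muA^2 / (alpha * q0^2 * length(a))
    szB <- muB^2 / (alpha * q0^2 * length(b))
    pa <- dnbinom(0:S, mu = muA, size = szA) *
      dnbinom(S:0, mu = muB, size = szB)
    sum(pa[pa <= pa[sum(a) + 1] * (1 + 1e-8)]) / sum(pa)
  }
  expect_equal(nb_test(c(12, 15, 9), c(30, 41), dispersion = 0.05),
               oracle_p(c(12, 15, 9), c(30, 41), 0.05), tolerance = 1e-10)

  expect_equal(nb_test(c(0, 0), c(0, 0)), 1)           # all-zero convention
  expect_gte(nb_test(c(20, 22), c(20, 22)), 0.99)      # identical groups
  expect_lt(nb_test(c(5, 6), c(50, 60)), 0.05)
  expect_error(nb_test(integer(0), c(1, 2)), "per group")
  expect_error(nb_test(c(1, 2), c(1, 2), size_factors = c(1, 1, -1, 1)),
               "positive")
})

test_that("NB test holds its nominal type-I error and gains power with effect size", {
  nrep <- 3
  n <- 2000
  m <- withr::with_seed(101,
                        matrix(rnbinom(n * 2 * nrep, mu = 100, size = 10),
                               nrow = n))
  cnt <- tibble::tibble(
    gene_id = rep(sprintf("g%04d", seq_len(n)), times = 2 * nrep),
    sample = rep(sprintf("s%d", seq_len(2 * nrep)), each = n),
    count = as.vector(m))
  res <- nb_test_genes(cnt, sprintf("s%d", 1:nrep),
                       sprintf("s%d", nrep + 1:nrep))
  expect_lt(abs(mean(res$pval < 0.05) - 0.05), 0.02)
  expect_true(all(res$pval > 0 & res$pval <= 1))

  power_at <- function(fc, seed) {
    n2 <- 250
    mm <- withr::with_seed(seed, cbind(
      matrix(rnbinom(n2 * nrep, mu = 100, size = 10), nrow = n2),
      matrix(rnbinom(n2 * nrep, mu = 100 * fc, size = 10), nrow = n2)))
    cc <- tibble::tibble(
      gene_id = rep(sprintf("g%03d", seq_len(n2)), times = 2 * nrep),
      sample = rep(sprintf("s%d", seq_len(2 * nrep)), each = n2),
      count = as.vector(mm))
    mean(nb_test_genes(cc, sprintf("s%d", 1:nrep),
                       sprintf("s%d", nrep + 1:nrep))$pval < 0.05)
  }
  pw <- c(power_at(1.5, 11), power_at(2.5, 12), power_at(6, 13))
  expect_true(all(diff(pw) > 0))
  expect_gt(pw[3], 0.8)
})

test_that("BH adjustment equals the long-hand step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(0.2, 6)), rep(0.2, 6))
  for (s in 1:25) {
    p <- withr::with_seed(s, runif(sample(1:50, 1)))
    expect_equal(bh_fdr(p), oracle_bh(p))
  }
})

test_that("nascent-gene filter applies all three cutoffs strictly", {
  apply_rule <- function(fdr, fpkm, ama) {
    fc <- if (ama == 0) (if (fpkm > 0) Inf else NaN) else fpkm / ama
    !is.na(fdr) && fdr < 0.05 && fpkm > 2 && !is.nan(fc) && fc > 2
  }
  grid <- expand.grid(fdr = c(0.01, 0.04, 0.05, 0.2),
                      fpkm = c(0.5, 2, 2.5, 10),
                      ama = c(0, 0.5, 1.19, 5))
  for (i in seq_len(nrow(grid))) {
    expect_equal(apply_rule(grid$fdr[i], grid$fpkm[i], grid$ama[i]),
                 oracle_nascent(grid$fdr[i], grid$fpkm[i], grid$ama[i]),
                 info = paste(grid[i, ], collapse = "/"))
  }

  # end-to-end on generated 2-cell data. The fold-change filter compares the
  # nascent signal against the maternal store, so detectability requires the
  # store not to drown the nascent component: run with a low store level and
  # expect near-complete recovery there.
  cfg <- small_config(size_factor_sd = 0.2, maternal_store_level = 2)
  tr <- generate_truth(cfg)
  e <- dplyr::bind_rows(generate_expression(tr, cfg, "two_cell_AG"),
                        generate_expression(tr, cfg, "two_cell_Ama"))
  ag_s <- unique(e$sample[e$stage == "two_cell_AG"])
  ama_s <- unique(e$sample[e$stage == "two_cell_Ama"])
  nas <- call_nascent(e, ag_s, ama_s)
  truth_nascent <- tr$gene_id[tr$expressed_allele %in% c("both", "paternal")]
  called <- nas$gene_id[nas$nascent]
  expect_gte(mean(called %in% truth_nascent), 0.9)
  expect_gte(mean(truth_nascent %in% called), 0.9)

  # a gene whose maternal store dwarfs its nascent transcription is masked:
  # the alpha-amanitin fold change cannot exceed 2
  hi_store <- small_config(size_factor_sd = 0, maternal_store_level = 500)
  tr2 <- generate_truth(hi_store)
  e2 <- dplyr::bind_rows(generate_expression(tr2, hi_store, "two_cell_AG"),
                         generate_expression(tr2, hi_store, "two_cell_Ama"))
  nas2 <- call_nascent(e2, unique(e2$sample[e2$stage == "two_cell_AG"]),
                       unique(e2$sample[e2$stage == "two_cell_Ama"]))
  expect_lt(mean(nas2$nascent), 0.25)
})

test_that("store-subtracted DEG calls follow the clamping conventions", {
  expect_equal(deg_call(22, 2, 1), "AG-specific")
  expect_equal(deg_call(10, 10, 1), "none")
  expect_equal(deg_call(0.5, 0, 1), "none")  # clamped numerator
  expect_equal(deg_call(5, 0, 0), "AG-specific")  # zero denominator passes
  expect_equal(deg_call(0, 0, 2), "none")
  expect_equal(deg_call(2, 23, 1), "GG-specific")
  # exactly 10-fold is not enough
  expect_equal(deg_call(11, 2, 1), "none")
  grid <- withr::with_seed(21, tibble::tibble(
    ag = round(runif(2000, 0, 30), 1),
    gg = round(runif(2000, 0, 30), 1),
    ama = round(runif(2000, 0, 5), 1)))
  got <- deg_call(grid$ag, grid$gg, grid$ama)
  want <- mapply(oracle_deg, grid$ag, grid$gg, grid$ama)
  expect_identical(got, unname(want))
})

test_that("morula bias classes use the printed thresholds", {
  expect_equal(morula_bias(4.1, 0.5), "highly biased")
  expect_equal(morula_bias(0.4, 0.3), "not expressed")
  expect_equal(morula_bias(0.5, 0.5), "not expressed")  # strict > 0.5
  expect_equal(morula_bias(10, 10), "unbiased")
  expect_equal(morula_bias(1.2, 0.6), "unbiased")       # FC exactly 2
  expect_equal(morula_bias(1.3, 0.6), "biased")
  expect_equal(morula_bias(8, 1), "biased")             # FC exactly 8
  expect_equal(morula_bias(c(3, 0.2), c(0.6, 0.1)), c("biased", "not expressed"))
})

test_that("derepression test flags planted non-canonical genes only", {
  cfg <- small_config(kdm6b_efficiency = 1)
  tr <- generate_truth(cfg)
  e <- dplyr::bind_rows(
    generate_expression(tr, cfg, "morula_PG_kdm6b_wt"),
    generate_expression(tr, cfg, "morula_PG_kdm6b_mut"))
  wt_s <- unique(e$sample[e$stage == "morula_PG_kdm6b_wt"])
  mut_s <- unique(e$sample[e$stage == "morula_PG_kdm6b_mut"])
  res <- derepression_test(e[!e$is_ercc, ], wt_s, mut_s,
                           size_factors = size_factors_ercc(e))
  cmp <- dplyr::inner_join(res, tr[, c("gene_id", "imprint_class")],
                           by = "gene_id")
  expect_true(all(cmp$derepressed[cmp$imprint_class == "non-canonical"]))
  expect_false(any(cmp$derepressed[cmp$imprint_class == "canonical"]))
  # identical arms can never be called derepressed
  e0 <- e[e$stage == "morula_PG_kdm6b_mut" & !e$is_ercc, ]
  e0w <- dplyr::mutate(e0, sample = sub("mut", "wtcopy", sample))
  res0 <- derepression_test(dplyr::bind_rows(e0, e0w),
                            unique(e0w$sample), unique(e0$sample))
  expect_false(any(res0$derepressed))
})

test_that("reciprocal-cross imprint calls separate strain from parent effects", {
  expect_equal(imprint_call(5, 30, 8, 40), "PEG")
  expect_equal(imprint_call(30, 5, 40, 8), "MEG")
  # 19 total reads in one cross: not determined
  expect_equal(imprint_call(5, 14, 40, 8), "N.D.")
  # bias in one cross only: a strain effect, not imprinting
  expect_equal(imprint_call(5, 30, 40, 8), "not imprinted")
  # pure strain effect fixture: same strain allele up in both crosses
  expect_equal(imprint_call(10, 40, 40, 10), "not imprinted")
  expect_equal(imprint_call(0, 30, 0, 25), "PEG")  # infinite ratios
  expect_error(imprint_call(-1, 5, 5, 5), "non-negative")

  grid <- withr::with_seed(31, tibble::tibble(
    bm = rpois(4000, 12), bp = rpois(4000, 12),
    pm = rpois(4000, 12), pp = rpois(4000, 12)))
  got <- imprint_call(grid$bm, grid$bp, grid$pm, grid$pp)
  want <- mapply(oracle_imprint, grid$bm, grid$bp, grid$pm, grid$pp)
  expect_identical(got, unname(want))

  tab <- tibble::tibble(gene_id = rep(c("gA", "gB"), each = 2),
                        cross = rep(c("BxP", "PxB"), 2),
                        mat_reads = c(5, 8, 100, 90),
                        pat_reads = c(30, 40, 95, 100))
  res <- call_imprinted_reciprocal(tab)
  expect_equal(res$status, c("PEG", "not imprinted"))
  # the injection context lowers the read minimum to 10
  expect_equal(imprint_call(4, 10, 3, 9, min_snp_reads = 10), "PEG")
  expect_equal(imprint_call(4, 10, 3, 9, min_snp_reads = 20), "N.D.")
})

test_that("AG-specific DEGs are a subset of nascent AG genes", {
  # the subset holds when nascent transcription dominates the residual
  # store, the regime the subtraction step is designed for
  cfg <- small_config(size_factor_sd = 0.2, maternal_store_level = 2)
  tr <- generate_truth(cfg)
  e <- dplyr::bind_rows(generate_expression(tr, cfg, "two_cell_AG"),
                        generate_expression(tr, cfg, "two_cell_GG"),
                        generate_expression(tr, cfg, "two_cell_Ama"))
  sf <- size_factors_ercc(e)
  ag_s <- unique(e$sample[e$stage == "two_cell_AG"])
  ama_s <- unique(e$sample[e$stage == "two_cell_Ama"])
  nas <- call_nascent(e, ag_s, ama_s, size_factors = sf)
  fp <- fpkm(e[!e$is_ercc, ], sf)
  means <- fp |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(ag_fpkm = mean(fpkm[stage == "two_cell_AG"]),
                     gg_fpkm = mean(fpkm[stage == "two_cell_GG"]),
                     ama_fpkm = mean(fpkm[stage == "two_cell_Ama"]),
                     .groups = "drop")
  degs <- call_allelic_deg(means)
  ag_degs <- degs$gene_id[degs$deg_class == "AG-specific"]
  expect_gt(length(ag_degs), 0)
  expect_true(all(ag_degs %in% nas$gene_id[nas$nascent]))
})
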