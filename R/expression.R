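#' ERCC-anchored library size factors (median-of-ratios)
#'
#' Estimates one positive scale factor per sample using spike-in rows only:
#' for each ERCC row with all-positive counts, the ratio of each sample's
#' count to the row's geometric mean is formed, and the per-sample median
#' of those ratios is the size factor. Endogenous genes never enter the
#' estimator, so a genuine global shift in embryonic transcription (as at
#' zygotic genome activation) is preserved rather than normalised away.
#'
#' @param counts Long tibble with `gene_id`, `sample`, `count` and either
#'   an `is_ercc` column or `"ERCC"`-prefixed spike-in `gene_id`s.
#' @return A tibble `sample`, `size_factor`.
#' @export
size_factors_ercc <- function(counts) {
  if (!"is_ercc" %in% names(counts)) {
    counts$is_ercc <- startsWith(counts$gene_id, "ERCC")
  }
  ercc <- counts[counts$is_ercc, c("gene_id", "sample", "count")]
  if (nrow(ercc) == 0) stop("no ERCC rows found", call. = FALSE)
  wide <- tidyr::pivot_wider(ercc, names_from = "sample",
                             values_from = "count")
  m <- as.matrix(wide[, -1, drop = FALSE])
  usable <- rowSums(m > 0) == ncol(m)
  if (!any(usable)) {
    stop("no ERCC row has positive counts in all samples", call. = FALSE)
  }
  logratios <- log(m[usable, , drop = FALSE]) -
    rowMeans(log(m[usable, , drop = FALSE]))
  tibble::tibble(sample = colnames(m),
                 size_factor = unname(exp(apply(logratios, 2, stats::median))))
}

#' Normalised FPKM from a count table
#'
#' Divides counts by the per-sample size factor, then expresses each gene
#' per kilobase of exonic length and per million normalised mapped
#' fragments. The per-million denominator is *common* to all samples (the
#' mean of the per-sample normalised totals): after ERCC anchoring,
#' genuine global differences in transcript amount between samples — the
#' very signal an alpha-amanitin comparison measures — must survive
#' normalisation, which per-sample totals would silently remove.
#'
#' @param counts Long tibble with `gene_id`, `sample`, `count`,
#'   `exonic_length`.
#' @param size_factors Tibble `sample`, `size_factor` (e.g. from
#'   [size_factors_ercc()]); `NULL` for unit factors.
#' @return `counts` with `norm_count` and `fpkm` columns added.
#' @export
fpkm <- function(counts, size_factors = NULL) {
  if (is.null(size_factors)) {
    size_factors <- tibble::tibble(sample = unique(counts$sample),
                                   size_factor = 1)
  }
  if (any(size_factors$size_factor <= 0)) {
    stop("size factors must be positive", call. = FALSE)
  }
  out <- counts |>
    dplyr::inner_join(size_factors, by = "sample") |>
    dplyr::mutate(norm_count = .data$count / .data$size_factor)
  totals <- tapply(out$norm_count, out$sample, sum)
  out |>
    dplyr::mutate(
      fpkm = .data$norm_count / (.data$exonic_length / 1000) /
        (mean(totals) / 1e6)
    ) |>
    dplyr::select(-"size_factor")
}

# Exact conditioned two-group NB p-value for group sums kA, kB with group-sum
# means muA, muB and a common dispersion alpha on the per-sample scale.
# varA = muA + alpha * q0^2 * sum(sfA^2); the group sum is treated as NB with
# that mean and variance. p = probability, conditional on the overall total,
# of an allocation as or less likely than the observed one.
nb_exact_p <- function(kA, kB, muA, muB, varA, varB) {
  S <- kA + kB
  a <- 0:S
  dens <- function(x, mu, v) {
    if (v <= mu * (1 + 1e-12)) return(stats::dpois(x, mu))
    stats::dnbinom(x, mu = mu, size = mu^2 / (v - mu))
  }
  pa <- dens(a, muA, varA) * dens(S - a, muB, varB)
  tot <- sum(pa)
  if (tot == 0) return(1)
  pobs <- pa[kA + 1]
  min(1, sum(pa[pa <= pobs * (1 + 1e-8)]) / tot)
}

# Method-of-moments dispersion for one gene from normalised counts q and
# size factors sf; can be negative (shot noise exceeds biological noise).
mom_dispersion <- function(q, sf) {
  qbar <- mean(q)
  if (qbar <= 0) return(NA_real_)
  (stats::var(q) - qbar * mean(1 / sf)) / qbar^2
}

#' Exact negative-binomial test for one gene
#'
#' Two-sided test of equal expression between two small groups of counts,
#' in the style of the classic conditioned NB exact test: per-sample counts
#' are modelled NB with common mean (after size-factor normalisation) and
#' common dispersion `alpha` (variance `mu + alpha mu^2`); the p-value sums
#' the probabilities of all allocations of the observed grand total between
#' the two group sums that are no more likely than the observed allocation.
#' Dispersion defaults to a floored method-of-moments estimate pooled
#' across both groups; pass `dispersion` to fix it. An all-zero gene
#' returns `p = 1` by convention.
#'
#' @param counts_a,counts_b Integer count vectors for the two groups.
#' @param size_factors Positive per-sample factors, length
#'   `length(counts_a) + length(counts_b)` (a-samples first); `NULL` for 1.
#' @param dispersion Optional fixed dispersion alpha.
#' @param dispersion_floor Lower bound applied to estimated dispersions.
#' @return A two-sided p-value in (0, 1].
#' @export
nb_test <- function(counts_a, counts_b, size_factors = NULL,
                    dispersion = NULL, dispersion_floor = 1e-8) {
  na <- length(counts_a)
  nb <- length(counts_b)
  if (na + nb < 2 || na < 1 || nb < 1) {
    stop("need at least one sample per group", call. = FALSE)
  }
  if (is.null(size_factors)) size_factors <- rep(1, na + nb)
  if (length(size_factors) != na + nb || any(size_factors <= 0)) {
    stop("size_factors must be positive and match the sample count",
         call. = FALSE)
  }
  kA <- sum(counts_a)
  kB <- sum(counts_b)
  if (kA + kB == 0) return(1)
  sfa <- size_factors[seq_len(na)]
  sfb <- size_factors[na + seq_len(nb)]
  q0 <- (kA + kB) / sum(size_factors)
  if (is.null(dispersion)) {
    q <- c(counts_a, counts_b) / size_factors
    dispersion <- mom_dispersion(q, size_factors)
    dispersion <- max(dispersion, dispersion_floor, na.rm = TRUE)
  }
  muA <- q0 * sum(sfa)
  muB <- q0 * sum(sfb)
  nb_exact_p(kA, kB, muA, muB,
             muA + dispersion * q0^2 * sum(sfa^2),
             muB + dispersion * q0^2 * sum(sfb^2))
}

#' Per-gene exact NB tests for a count table
#'
#' Runs [nb_test()] on every gene of a long count table, with dispersions
#' shared across genes: per-gene method-of-moments estimates are used to
#' fit a mean--dispersion trend `alpha(mu) = a0 + a1/mu`, and the fitted
#' trend value is each gene's working dispersion (fit-only sharing, which
#' keeps the test's type-I error at its nominal level with the few
#' replicates typical of embryo experiments; taking the per-gene maximum
#' against the trend instead makes the exact test markedly conservative).
#' Benjamini-Hochberg adjusted values are included.
#'
#' @param counts Long tibble `gene_id`, `sample`, `count`.
#' @param samples_a,samples_b Sample names of the two groups.
#' @param size_factors Tibble `sample`, `size_factor`, or `NULL` for 1.
#' @param dispersion Optional fixed dispersion for all genes.
#' @return A tibble `gene_id`, `mean_a`, `mean_b` (normalised means),
#'   `dispersion`, `pval`, `padj`.
#' @export
nb_test_genes <- function(counts, samples_a, samples_b,
                          size_factors = NULL, dispersion = NULL) {
  all_samples <- c(samples_a, samples_b)
  if (is.null(size_factors)) {
    size_factors <- tibble::tibble(sample = all_samples, size_factor = 1)
  }
  sf <- stats::setNames(size_factors$size_factor, size_factors$sample)[all_samples]
  if (anyNA(sf)) stop("size factors missing for some samples", call. = FALSE)

  wide <- counts |>
    dplyr::filter(.data$sample %in% all_samples) |>
    dplyr::select(dplyr::all_of(c("gene_id", "sample", "count"))) |>
    tidyr::pivot_wider(names_from = "sample", values_from = "count")
  m <- as.matrix(wide[, all_samples, drop = FALSE])
  ia <- seq_along(samples_a)
  ib <- length(samples_a) + seq_along(samples_b)

  q <- sweep(m, 2, sf, "/")
  if (is.null(dispersion)) {
    raw <- apply(q, 1, mom_dispersion, sf = sf)
    mu <- rowMeans(q)
    use <- !is.na(raw) & raw > 0 & mu > 0
    alpha <- if (sum(use) >= 10) {
      fit <- stats::lm(a ~ x, data = data.frame(a = raw[use], x = 1 / mu[use]))
      pmax(stats::predict(fit, newdata = data.frame(x = 1 / pmax(mu, 1e-8))),
           1e-8)
    } else {
      rep(max(suppressWarnings(stats::median(raw[use])), 1e-8, na.rm = TRUE),
          nrow(m))
    }
  } else {
    alpha <- rep(dispersion, nrow(m))
  }

  pval <- vapply(seq_len(nrow(m)), function(i) {
    nb_test(m[i, ia], m[i, ib], size_factors = sf, dispersion = alpha[i])
  }, numeric(1))

  tibble::tibble(
    gene_id = wide$gene_id,
    mean_a = rowMeans(q[, ia, drop = FALSE]),
    mean_b = rowMeans(q[, ib, drop = FALSE]),
    dispersion = alpha,
    pval = pval,
    padj = bh_fdr(pval)
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; a thin wrapper over
#' [stats::p.adjust()] with `method = "BH"` so the pipeline's FDR
#' convention is named once.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted values, same length.
#' @export
bh_fdr <- function(p) stats::p.adjust(p, method = "BH")

#' Call nascent (newly synthesised) genes against alpha-amanitin controls
#'
#' A gene is nascent in AG (or GG) 2-cell embryos when its expression
#' differs significantly from the transcription-inhibited alpha-amanitin
#' control (exact NB test, BH-FDR < `fdr_max`), its mean FPKM in the
#' treated group exceeds `fpkm_min`, and its fold change over the
#' alpha-amanitin mean exceeds `fc_min` (all strict).
#'
#' @param counts Long tibble with `gene_id`, `sample`, `count`,
#'   `exonic_length` and ERCC rows (used for size factors when
#'   `size_factors` is `NULL`). ERCC rows are excluded from the calls.
#' @param nascent_samples,ama_samples Sample names of the treated (AG or
#'   GG) and alpha-amanitin groups.
#' @param size_factors Optional tibble `sample`, `size_factor`.
#' @param fdr_max,fpkm_min,fc_min Cutoffs (defaults 0.05, 2, 2).
#' @return A tibble `gene_id`, `padj`, `mean_fpkm`, `ama_fpkm`, `fc`,
#'   `nascent` (logical).
#' @export
call_nascent <- function(counts, nascent_samples, ama_samples,
                         size_factors = NULL,
                         fdr_max = 0.05, fpkm_min = 2, fc_min = 2) {
  if (is.null(size_factors)) size_factors <- size_factors_ercc(counts)
  if (!"is_ercc" %in% names(counts)) {
    counts$is_ercc <- startsWith(counts$gene_id, "ERCC")
  }
  genes <- counts[!counts$is_ercc, ]
  fp <- fpkm(genes, size_factors)
  mean_fp <- fp |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      mean_fpkm = mean(.data$fpkm[.data$sample %in% nascent_samples]),
      ama_fpkm = mean(.data$fpkm[.data$sample %in% ama_samples]),
      .groups = "drop"
    )
  tests <- nb_test_genes(genes, nascent_samples, ama_samples,
                         size_factors = size_factors)
  mean_fp |>
    dplyr::inner_join(tests[, c("gene_id", "padj")], by = "gene_id") |>
    dplyr::mutate(
      fc = dplyr::if_else(.data$ama_fpkm == 0,
                          dplyr::if_else(.data$mean_fpkm > 0, Inf, NaN),
                          .data$mean_fpkm / .data$ama_fpkm),
      nascent = !is.na(.data$padj) & .data$padj < fdr_max &
        .data$mean_fpkm > fpkm_min &
        !is.nan(.data$fc) & .data$fc > fc_min
    ) |>
    dplyr::relocate("padj", .after = "gene_id")
}

#' Maternal-store-subtracted allelic DEG call for one gene
#'
#' Subtracts the alpha-amanitin (maternally stored) FPKM from the AG and
#' GG values, clamping negatives to zero, and calls the gene AG-specific
#' when the subtracted AG/GG ratio exceeds `fc_min` (GG-specific
#' symmetrically). A zero denominator with a positive numerator passes
#' (infinite fold change); both zero is no call.
#'
#' @param ag_fpkm,gg_fpkm,ama_fpkm FPKM values (vectorised).
#' @param fc_min Fold-change cutoff (default 10, strict).
#' @return Character vector in `{"AG-specific", "GG-specific", "none"}`.
#' @export
deg_call <- function(ag_fpkm, gg_fpkm, ama_fpkm, fc_min = 10) {
  a <- pmax(ag_fpkm - ama_fpkm, 0)
  g <- pmax(gg_fpkm - ama_fpkm, 0)
  dplyr::case_when(
    a > 0 & g == 0 ~ "AG-specific",
    g > 0 & a == 0 ~ "GG-specific",
    a == 0 & g == 0 ~ "none",
    a / g > fc_min ~ "AG-specific",
    g / a > fc_min ~ "GG-specific",
    .default = "none"
  )
}

#' Call AG- and GG-specific DEGs from per-gene FPKMs
#'
#' @param expr Tibble with `gene_id`, `ag_fpkm`, `gg_fpkm`, `ama_fpkm`.
#' @inheritParams deg_call
#' @return `expr` with `ag_sub`, `gg_sub` (store-subtracted values),
#'   `fold_change` and `deg_class` columns.
#' @export
call_allelic_deg <- function(expr, fc_min = 10) {
  expr |>
    dplyr::mutate(
      ag_sub = pmax(.data$ag_fpkm - .data$ama_fpkm, 0),
      gg_sub = pmax(.data$gg_fpkm - .data$ama_fpkm, 0),
      fold_change = pmax(.data$ag_sub, .data$gg_sub) /
        pmin(.data$ag_sub, .data$gg_sub),
      deg_class = deg_call(.data$ag_fpkm, .data$gg_fpkm, .data$ama_fpkm,
                           fc_min = fc_min)
    )
}

#' Classify AG/GG expression bias at the morula stage
#'
#' `not expressed` when neither uniparental embryo reaches
#' `expressed_min` FPKM; otherwise `biased` when the larger/smaller ratio
#' exceeds `fc_biased`, `highly biased` when it exceeds `fc_high`
#' (a subset of biased, reported as its own label), else `unbiased`.
#'
#' @param ag_fpkm,gg_fpkm Per-gene mean FPKM in AG and GG embryos
#'   (vectorised).
#' @param expressed_min,fc_biased,fc_high Cutoffs (defaults 0.5, 2, 8; all
#'   strict).
#' @return Character vector in `{"not expressed", "unbiased", "biased",
#'   "highly biased"}`.
#' @export
morula_bias <- function(ag_fpkm, gg_fpkm, expressed_min = 0.5,
                        fc_biased = 2, fc_high = 8) {
  hi <- pmax(ag_fpkm, gg_fpkm)
  lo <- pmin(ag_fpkm, gg_fpkm)
  fc <- ifelse(lo == 0, ifelse(hi > 0, Inf, NaN), hi / lo)
  dplyr::case_when(
    hi <= expressed_min ~ "not expressed",
    fc > fc_high ~ "highly biased",
    fc > fc_biased ~ "biased",
    .default = "unbiased"
  )
}

#' Test candidate genes for derepression by a demethylase
#'
#' Per candidate gene, tests Kdm6b-WT against catalytic-mutant counts with
#' the exact NB test; a gene is derepressed when its BH-FDR (across the
#' candidates) is below `fdr_max` and its normalised WT mean exceeds the
#' mutant mean.
#'
#' @param counts Long tibble `gene_id`, `sample`, `count`.
#' @param wt_samples,mut_samples Sample names of the two arms.
#' @param size_factors Optional tibble `sample`, `size_factor`.
#' @param candidate_genes Genes to test (others are ignored).
#' @param fdr_max FDR cutoff (default 0.05).
#' @return A tibble `gene_id`, `mean_wt`, `mean_mut`, `pval`, `padj`,
#'   `derepressed`.
#' @export
derepression_test <- function(counts, wt_samples, mut_samples,
                              size_factors = NULL, candidate_genes = NULL,
                              fdr_max = 0.05) {
  if (!is.null(candidate_genes)) {
    counts <- counts[counts$gene_id %in% candidate_genes, ]
  }
  res <- nb_test_genes(counts, wt_samples, mut_samples,
                       size_factors = size_factors)
  res |>
    dplyr::rename(mean_wt = "mean_a", mean_mut = "mean_b") |>
    dplyr::mutate(derepressed = .data$padj < fdr_max &
                    .data$mean_wt > .data$mean_mut)
}

#' Parental imprint call from reciprocal crosses
#'
#' A gene is a paternally expressed gene (PEG) when its paternal/maternal
#' SNP-read ratio exceeds `fc_min` in *both* reciprocal crosses (and MEG
#' symmetrically): requiring both crosses separates a parent-of-origin
#' effect from a strain effect, which flips parental labels between
#' crosses. A gene is `N.D.` when either cross has fewer than
#' `min_snp_reads` total SNP reads.
#'
#' @param bxp_mat,bxp_pat,pxb_mat,pxb_pat Per-gene maternal/paternal SNP
#'   read counts in the two crosses (vectorised).
#' @param min_snp_reads Minimum total SNP reads per cross (default 20; the
#'   demethylase-injection analysis uses 10).
#' @param fc_min Allelic fold-change cutoff (default 2, strict).
#' @return Character vector in `{"PEG", "MEG", "not imprinted", "N.D."}`.
#' @export
imprint_call <- function(bxp_mat, bxp_pat, pxb_mat, pxb_pat,
                         min_snp_reads = 20, fc_min = 2) {
  if (any(c(bxp_mat, bxp_pat, pxb_mat, pxb_pat) < 0)) {
    stop("SNP read counts must be non-negative", call. = FALSE)
  }
  ratio <- function(num, den) ifelse(den == 0, ifelse(num > 0, Inf, NaN),
                                     num / den)
  pat_fc_1 <- ratio(bxp_pat, bxp_mat)
  pat_fc_2 <- ratio(pxb_pat, pxb_mat)
  mat_fc_1 <- ratio(bxp_mat, bxp_pat)
  mat_fc_2 <- ratio(pxb_mat, pxb_pat)
  dplyr::case_when(
    bxp_mat + bxp_pat < min_snp_reads |
      pxb_mat + pxb_pat < min_snp_reads ~ "N.D.",
    pat_fc_1 > fc_min & pat_fc_2 > fc_min ~ "PEG",
    mat_fc_1 > fc_min & mat_fc_2 > fc_min ~ "MEG",
    .default = "not imprinted"
  )
}

#' Call imprinted genes from a reciprocal-cross allelic read table
#'
#' @param allelic Tibble with `gene_id`, `cross` (`"BxP"`/`"PxB"`),
#'   `mat_reads`, `pat_reads` (one row per gene and cross).
#' @inheritParams imprint_call
#' @return One row per gene with both crosses' counts and `status`.
#' @export
call_imprinted_reciprocal <- function(allelic, min_snp_reads = 20,
                                      fc_min = 2) {
  wide <- allelic |>
    tidyr::pivot_wider(id_cols = "gene_id", names_from = "cross",
                       values_from = c("mat_reads", "pat_reads"))
  needed <- c("mat_reads_BxP", "pat_reads_BxP", "mat_reads_PxB", "pat_reads_PxB")
  missing <- setdiff(needed, names(wide))
  if (length(missing) > 0) {
    stop("both BxP and PxB crosses are required", call. = FALSE)
  }
  wide |>
    dplyr::mutate(status = imprint_call(
      .data$mat_reads_BxP, .data$pat_reads_BxP,
      .data$mat_reads_PxB, .data$pat_reads_PxB,
      min_snp_reads = min_snp_reads, fc_min = fc_min))
}
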