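#' Mean methylation of an interval from a per-CpG profile
#'
#' Coverage-weighted mean CpG methylation over each interval extended by
#' `extend_bp` up- and downstream (window clamped at position 0) — the
#' extension pulls in nearby CpGs so short accessibility peaks get enough
#' bisulfite coverage. Intervals with no covered CpG in the window get
#' `NA` ("undefined" is a value, not an error).
#'
#' @param profile Per-CpG tibble `chrom`, `start`, (`end`,) `level`
#'   (fraction in `[0, 1]`), `coverage`.
#' @param intervals Tibble `chrom`, `start`, `end`.
#' @param extend_bp Window extension in bp (default 2000).
#' @param min_coverage Minimum per-CpG coverage to include (default 1).
#' @return `intervals` with a `meth_mean` column.
#' @export
interval_methylation <- function(profile, intervals, extend_bp = 2000,
                                 min_coverage = 1) {
  check_intervals(intervals)
  if (any(profile$level < 0 | profile$level > 1)) {
    stop("methylation levels must be in [0, 1]", call. = FALSE)
  }
  prof <- profile[profile$coverage >= min_coverage, ]
  meth <- vapply(seq_len(nrow(intervals)), function(i) {
    lo <- max(0, intervals$start[i] - extend_bp)
    hi <- intervals$end[i] + extend_bp
    sel <- prof$chrom == intervals$chrom[i] & prof$start >= lo & prof$start < hi
    if (!any(sel)) return(NA_real_)
    stats::weighted.mean(prof$level[sel], prof$coverage[sel])
  }, numeric(1))
  dplyr::mutate(intervals, meth_mean = meth)
}

#' Classify a locus as a germline DMR from gamete methylation means
#'
#' An oocyte-methylated gDMR has more than 80% methylation in oocytes and
#' less than 20% in sperm (strict inequalities, exactly as the definition
#' is stated — a locus at exactly 80% is not a gDMR); a sperm gDMR is the
#' mirror image.
#'
#' @param oocyte_mean,sperm_mean Mean methylation fractions (vectorised).
#' @param hyper_min,hypo_max Cutoffs (defaults 0.8 and 0.2).
#' @return Character vector in `{"oocyte gDMR", "sperm gDMR", "none"}`
#'   (`NA` where either input is `NA`).
#' @export
classify_gdmr <- function(oocyte_mean, sperm_mean,
                          hyper_min = 0.8, hypo_max = 0.2) {
  dplyr::case_when(
    is.na(oocyte_mean) | is.na(sperm_mean) ~ NA_character_,
    oocyte_mean > hyper_min & sperm_mean < hypo_max ~ "oocyte gDMR",
    sperm_mean > hyper_min & oocyte_mean < hypo_max ~ "sperm gDMR",
    .default = "none"
  )
}

#' Oocyte methylation class of a locus
#'
#' Buckets the oocyte methylation mean into the hypomethylated (0-20%,
#' closed interval: exactly 0.20 is still hypo) and hypermethylated
#' (80-100%, closed) groups used to split paternal-specific DHSs by their
#' oocyte DNA methylation; everything between is `intermediate`. Note the
#' deliberate contrast with [classify_gdmr()], whose cutoffs are strict:
#' the two rules are stated differently and are implemented differently.
#'
#' @param oocyte_mean Mean oocyte methylation fraction (vectorised).
#' @param hypo_max,hyper_min Class boundaries (defaults 0.2 and 0.8,
#'   inclusive).
#' @return Character vector in `{"hypo", "intermediate", "hyper",
#'   "undefined"}` (`"undefined"` for `NA` input).
#' @export
methylation_class <- function(oocyte_mean, hypo_max = 0.2, hyper_min = 0.8) {
  dplyr::case_when(
    is.na(oocyte_mean) ~ "undefined",
    oocyte_mean <= hypo_max ~ "hypo",
    oocyte_mean >= hyper_min ~ "hyper",
    .default = "intermediate"
  )
}

#' Associate intervals with nearby germline DMRs
#'
#' Labels each interval `overlapping` when it intersects a gDMR directly,
#' `associated` when any 1-kb bin tiling the `flank_bp` regions on either
#' side intersects a gDMR (flanks are tiled with `floor(flank_bp/bin_bp)`
#' whole bins), and `none` otherwise. Association is monotone in
#' `flank_bp`: enlarging the flank never loses an association.
#'
#' @param intervals Tibble `chrom`, `start`, `end`.
#' @param gdmrs Tibble of gDMR intervals (`chrom`, `start`, `end`).
#' @param flank_bp Flanking distance on each side (default 100000).
#' @param bin_bp Bin width used to tile the flanks (default 1000).
#' @return `intervals` with a `gdmr_association` column.
#' @export
neighborhood_gdmr_association <- function(intervals, gdmrs,
                                          flank_bp = 100000, bin_bp = 1000) {
  check_intervals(intervals)
  if (nrow(gdmrs) > 0) check_intervals(gdmrs, "gdmrs")
  eff <- floor(flank_bp / bin_bp) * bin_bp
  overlapping <- overlaps_any(intervals$chrom, intervals$start,
                              intervals$end, gdmrs)
  flank_hit <- overlaps_any(intervals$chrom,
                            pmax(0, intervals$start - eff),
                            intervals$end + eff, gdmrs)
  dplyr::mutate(intervals, gdmr_association = dplyr::case_when(
    overlapping ~ "overlapping",
    flank_hit ~ "associated",
    .default = "none"
  ))
}

# Stage-specific fold-change cutoffs for maternal H3K27me3 bias: the ICM
# criterion is FC(Mat/Pat) > 2, the zygote criterion is the stricter > 4.
chip_stage_fc <- c(icm = 2, zygote = 4)

#' Maternal H3K27me3 bias call for allelic ChIP signal
#'
#' An interval harbours maternal allele-biased H3K27me3 when the maternal
#' RPM (computed over the interval +/- 1 kb) exceeds `rpm_min` and the
#' maternal/paternal fold change exceeds the stage cutoff: more than 2 in
#' blastocyst ICM, more than 4 in zygotes. A zero paternal RPM with a
#' passing maternal RPM gives an infinite fold change and passes. The
#' zygote criterion nests inside the ICM criterion: any signal passing at
#' the zygote stage would also pass at ICM.
#'
#' @param mat_rpm,pat_rpm Allelic RPM values (vectorised).
#' @param stage `"icm"` or `"zygote"`.
#' @param rpm_min Maternal RPM gate (default 0.5, strict).
#' @param fc_min Override of the stage fold-change cutoff.
#' @return Logical vector: maternal-biased or not.
#' @export
chip_allelic_bias <- function(mat_rpm, pat_rpm, stage = c("icm", "zygote"),
                              rpm_min = 0.5, fc_min = NULL) {
  stage <- match.arg(stage)
  if (is.null(fc_min)) fc_min <- chip_stage_fc[[stage]]
  fc <- ifelse(pat_rpm == 0, ifelse(mat_rpm > 0, Inf, NaN),
               mat_rpm / pat_rpm)
  mat_rpm > rpm_min & !is.nan(fc) & fc > fc_min
}
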