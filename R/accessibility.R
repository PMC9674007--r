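#' Merge DHS peak sets into a union of non-overlapping intervals
#'
#' Takes one or more BED-style peak tables and returns the sorted union of
#' overlapping or book-ended intervals (half-open coordinates), the way
#' peak sets from many libraries are merged into one common DHS catalogue.
#'
#' @param peaks A tibble with `chrom`, `start`, `end`, or a list of such
#'   tibbles.
#' @return A sorted tibble of non-overlapping `chrom`, `start`, `end`.
#' @export
merge_intervals <- function(peaks) {
  if (is.data.frame(peaks)) peaks <- list(peaks)
  all <- dplyr::bind_rows(lapply(peaks, function(p) {
    check_intervals(p)
    p[, c("chrom", "start", "end")]
  }))
  if (nrow(all) == 0) return(all)
  merged <- lapply(split(all, all$chrom), function(d) {
    # half-open -> 1-based closed; book-ended intervals become adjacent and
    # IRanges::reduce merges them, matching bedtools merge defaults
    r <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    tibble::tibble(chrom = d$chrom[1],
                   start = IRanges::start(r) - 1L,
                   end = IRanges::end(r))
  })
  dplyr::arrange(dplyr::bind_rows(merged), .data$chrom, .data$start)
}

#' Reads per kilobase per million mapped reads
#'
#' `count / ((length_bp / 1000) * (library_size / 1e6))` — the density of a
#' tag falling on a position, per 1 kb of interval per million mapped reads.
#'
#' @param count Read counts (vectorised).
#' @param length_bp Interval lengths in bp, all `> 0`.
#' @param library_size Total mapped reads per sample, all `> 0`.
#' @return Numeric RPKM values.
#' @export
rpkm <- function(count, length_bp, library_size) {
  if (any(length_bp <= 0)) stop("length_bp must be > 0", call. = FALSE)
  if (any(library_size <= 0)) stop("library_size must be > 0", call. = FALSE)
  count / ((length_bp / 1000) * (library_size / 1e6))
}

#' Pairwise Pearson correlation between replicate signal profiles
#'
#' Computes the Pearson correlation coefficient of per-feature tag
#' densities between every pair of samples — the replicate-reproducibility
#' QC used for genome-wide DHS profiles.
#'
#' @param quant Long tibble with `feature_id`, `sample`, `value`.
#' @return A tibble `sample_a`, `sample_b`, `r` covering all ordered pairs
#'   (symmetric; `r = 1` on the diagonal).
#' @export
replicate_qc <- function(quant) {
  wide <- tidyr::pivot_wider(quant[, c("feature_id", "sample", "value")],
                             names_from = "sample", values_from = "value")
  m <- stats::cor(as.matrix(wide[, -1, drop = FALSE]), method = "pearson")
  tibble::as_tibble(as.data.frame.table(m, responseName = "r",
                                        stringsAsFactors = FALSE)) |>
    dplyr::rename(sample_a = "Var1", sample_b = "Var2")
}

#' Classify one locus from per-replicate allelic RPKMs
#'
#' The stringent allele-specific rule: a biased allele must have mean
#' RPKM > 2 and RPKM > 1 in every replicate, with a mean fold change
#' larger than 4 over the other allele (all strict). `bi-allelic` requires
#' both alleles to pass mean > 2 and min > 1 with neither direction
#' exceeding fold change 4; anything else is `unclassified`, and
#' sex-chromosome loci are `excluded` outright. A zero minor-allele mean
#' gives an infinite fold change (no pseudocount), which passes the cutoff.
#'
#' @param mat,pat Numeric vectors of per-replicate RPKMs (equal length,
#'   at least 2 replicates each).
#' @param sex_chrom Is the locus on a sex chromosome?
#' @param mean_min,rep_min,fc_min The three cutoffs (defaults 2, 1, 4).
#' @return One of `"paternal-specific"`, `"maternal-specific"`,
#'   `"bi-allelic"`, `"unclassified"`, `"excluded"`.
#' @export
allelic_dhs_call <- function(mat, pat, sex_chrom = FALSE,
                             mean_min = 2, rep_min = 1, fc_min = 4) {
  if (length(mat) != length(pat)) {
    stop("replicate count mismatch between alleles", call. = FALSE)
  }
  if (length(mat) < 2) stop("need >= 2 replicates per allele", call. = FALSE)
  if (sex_chrom) return("excluded")
  mm <- mean(mat)
  pm <- mean(pat)
  fc_pat <- if (mm == 0) (if (pm > 0) Inf else NaN) else pm / mm
  fc_mat <- if (pm == 0) (if (mm > 0) Inf else NaN) else mm / pm
  pat_pass <- pm > mean_min && min(pat) > rep_min
  mat_pass <- mm > mean_min && min(mat) > rep_min
  if (pat_pass && !is.nan(fc_pat) && fc_pat > fc_min) return("paternal-specific")
  if (mat_pass && !is.nan(fc_mat) && fc_mat > fc_min) return("maternal-specific")
  if (pat_pass && mat_pass && fc_pat <= fc_min && fc_mat <= fc_min) {
    return("bi-allelic")
  }
  "unclassified"
}

#' Classify allelic DHS status for a table of loci
#'
#' Applies [allelic_dhs_call()] per locus to a long per-replicate RPKM
#' table, as used to identify paternal- and maternal-specific DHSs in
#' zygotes (maternal vs paternal pronuclei) and in uniparental morulae
#' (GG vs AG libraries standing in for the maternal and paternal genomes).
#'
#' @param quant Long tibble with `locus_id`, `allele`
#'   (`"maternal"`/`"paternal"`), `replicate`, `rpkm`, and optionally
#'   `sex_chrom` (plus any interval columns, carried through).
#' @inheritParams allelic_dhs_call
#' @return One row per locus: interval columns, `mat_mean`, `pat_mean`,
#'   `fold_change` (major over minor allele), `class`.
#' @export
classify_allelic_dhs <- function(quant, mean_min = 2, rep_min = 1, fc_min = 4) {
  if (!"sex_chrom" %in% names(quant)) quant$sex_chrom <- FALSE
  carry <- intersect(c("chrom", "start", "end", "sex_chrom"), names(quant))
  quant |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("locus_id", carry)))) |>
    dplyr::summarise(
      mat_mean = mean(.data$rpkm[.data$allele == "maternal"]),
      pat_mean = mean(.data$rpkm[.data$allele == "paternal"]),
      class = allelic_dhs_call(.data$rpkm[.data$allele == "maternal"],
                               .data$rpkm[.data$allele == "paternal"],
                               sex_chrom = .data$sex_chrom[1],
                               mean_min = mean_min, rep_min = rep_min,
                               fc_min = fc_min),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      fold_change = pmax(.data$pat_mean, .data$mat_mean) /
        pmin(.data$pat_mean, .data$mat_mean)
    ) |>
    dplyr::relocate("fold_change", .before = "class")
}

#' Restrict paternal-specific DHSs to the most reliable subset
#'
#' Keeps only paternal-specific DHS calls whose paternal-allele RPKM
#' exceeds 1 in every replicate of the microinjected-zygote paternal
#' pronuclei (strict; a replicate exactly at 1 drops the locus). This is
#' the additional criterion that defines the reliable subset used for
#' demethylase-rescue scoring.
#'
#' @param calls Output of [classify_allelic_dhs()].
#' @param injected_pat Long tibble `locus_id`, `replicate`, `rpkm` from the
#'   injected-zygote paternal pronuclei.
#' @param rep_min Per-replicate cutoff (default 1).
#' @return The subset of `calls` rows, with a `reliable` flag column.
#' @export
reliable_subset <- function(calls, injected_pat, rep_min = 1) {
  ok <- injected_pat |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(reliable = all(.data$rpkm > rep_min), .groups = "drop")
  calls |>
    dplyr::filter(.data$class == "paternal-specific") |>
    dplyr::inner_join(ok, by = "locus_id") |>
    dplyr::filter(.data$reliable)
}

#' Score demethylase rescue of a paternal-specific DHS
#'
#' A reliable Ps-DHS is `rescued` (became bi-allelic) when, in the
#' demethylase-WT condition, the maternal allele opens — maternal mean
#' RPKM > `wt_mat_min` with a paternal/maternal fold change at most
#' `wt_fc_max` — while the catalytic-mutant condition still satisfies the
#' paternal-specific rule. Published rescue counts come without printed
#' "became bi-allelic" cutoffs, so this rule is this package's declared,
#' configurable convention.
#'
#' @param wt_mat,wt_pat,mut_mat,mut_pat Per-replicate RPKM vectors for the
#'   two alleles in the WT and catalytic-mutant injection arms.
#' @param wt_mat_min,wt_fc_max Rescue cutoffs (defaults 1 and 2).
#' @inheritParams allelic_dhs_call
#' @return `"rescued"` or `"not rescued"`.
#' @export
rescue_call <- function(wt_mat, wt_pat, mut_mat, mut_pat,
                        wt_mat_min = 1, wt_fc_max = 2,
                        mean_min = 2, rep_min = 1, fc_min = 4) {
  wt_mm <- mean(wt_mat)
  wt_pm <- mean(wt_pat)
  fc <- if (wt_mm == 0) Inf else wt_pm / wt_mm
  wt_biallelic <- wt_mm > wt_mat_min && fc <= wt_fc_max
  mut_ps <- allelic_dhs_call(mut_mat, mut_pat, mean_min = mean_min,
                             rep_min = rep_min, fc_min = fc_min) ==
    "paternal-specific"
  if (wt_biallelic && mut_ps) "rescued" else "not rescued"
}

#' Classify demethylase rescue for a table of reliable Ps-DHSs
#'
#' @param quant Long tibble with `locus_id`, `arm` (`"wt"`/`"mut"`),
#'   `allele` (`"maternal"`/`"paternal"`), `replicate`, `rpkm`.
#' @inheritParams rescue_call
#' @return One row per locus with WT/MUT allele means and `rescue`.
#' @export
classify_rescue <- function(quant, wt_mat_min = 1, wt_fc_max = 2,
                            mean_min = 2, rep_min = 1, fc_min = 4) {
  quant |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(
      wt_mat_mean = mean(.data$rpkm[.data$arm == "wt" & .data$allele == "maternal"]),
      wt_pat_mean = mean(.data$rpkm[.data$arm == "wt" & .data$allele == "paternal"]),
      mut_mat_mean = mean(.data$rpkm[.data$arm == "mut" & .data$allele == "maternal"]),
      mut_pat_mean = mean(.data$rpkm[.data$arm == "mut" & .data$allele == "paternal"]),
      rescue = rescue_call(
        .data$rpkm[.data$arm == "wt" & .data$allele == "maternal"],
        .data$rpkm[.data$arm == "wt" & .data$allele == "paternal"],
        .data$rpkm[.data$arm == "mut" & .data$allele == "maternal"],
        .data$rpkm[.data$arm == "mut" & .data$allele == "paternal"],
        wt_mat_min = wt_mat_min, wt_fc_max = wt_fc_max,
        mean_min = mean_min, rep_min = rep_min, fc_min = fc_min),
      .groups = "drop"
    )
}

#' Annotate intervals with genomic context
#'
#' Labels each interval `promoter` when it overlaps a window of
#' `promoter_halfwidth` bp around any TSS (default +/- 1 kb; the
#' DEG-association analyses use +/- 0.5 kb), flags CGI overlap, and
#' assigns a single context label with promoter taking precedence over CGI.
#'
#' @param intervals Tibble with `chrom`, `start`, `end`.
#' @param gene_models Tibble with `chrom`, `tss` (and `gene_id`).
#' @param cgi_intervals Optional tibble of CpG-island intervals.
#' @param promoter_halfwidth Half-width of the TSS window in bp.
#' @return `intervals` with logical `is_promoter`, `is_cgi` and a
#'   `context` label in `{"promoter", "CGI", "other"}`.
#' @export
annotate_context <- function(intervals, gene_models, cgi_intervals = NULL,
                             promoter_halfwidth = 1000) {
  check_intervals(intervals)
  prom <- tibble::tibble(chrom = gene_models$chrom,
                         start = pmax(0, gene_models$tss - promoter_halfwidth),
                         end = gene_models$tss + promoter_halfwidth + 1)
  is_prom <- overlaps_any(intervals$chrom, intervals$start, intervals$end, prom)
  is_cgi <- if (is.null(cgi_intervals) || nrow(cgi_intervals) == 0) {
    rep(FALSE, nrow(intervals))
  } else {
    overlaps_any(intervals$chrom, intervals$start, intervals$end, cgi_intervals)
  }
  intervals |>
    dplyr::mutate(
      is_promoter = is_prom,
      is_cgi = is_cgi,
      context = dplyr::case_when(is_prom ~ "promoter",
                                 is_cgi ~ "CGI",
                                 .default = "other")
    )
}
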