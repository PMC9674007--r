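#' Filter aligned reads by mapping quality and positional redundancy
#'
#' Removes reads with MAPQ at or below `mapq_max_removed` (strict `<=`,
#' i.e. a read with MAPQ exactly 10 is dropped under the default) and then
#' collapses redundant reads that mapped to the same location with the same
#' orientation, keeping one read per `(chrom, start, orientation)` — the
#' one with the lexicographically smallest `read_id`, so the survivor is
#' deterministic. Applying the filter twice equals applying it once.
#'
#' @param reads Tibble with at least `read_id`, `chrom`, `start`,
#'   `orientation`, `mapq`.
#' @param mapq_max_removed Reads with `mapq <= mapq_max_removed` are removed.
#' @return The filtered tibble, original column set preserved.
#' @export
filter_reads <- function(reads, mapq_max_removed = 10) {
  needed <- c("read_id", "chrom", "start", "orientation", "mapq")
  missing <- setdiff(needed, names(reads))
  if (length(missing) > 0) {
    stop(sprintf("reads must have columns %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  reads |>
    dplyr::filter(.data$mapq > mapq_max_removed) |>
    dplyr::arrange(.data$read_id) |>
    dplyr::distinct(.data$chrom, .data$start, .data$orientation,
                    .keep_all = TRUE)
}

#' Assign reads to their parental origin from strain SNPs
#'
#' For every read, each covered SNP position (a SNP is covered when its
#' position lies in `[start, end)`) whose observed base matches exactly one
#' parental strain base is informative. A read is `maternal` when all its
#' informative SNPs match the maternal strain (and there are at least
#' `min_informative` of them), `paternal` symmetrically, `conflicting` when
#' both strains are matched at different SNPs, and `unassigned` when no
#' covered SNP matches either strain (including reads covering no SNP, and
#' reads on chromosomes absent from the SNP table).
#'
#' In a reciprocal cross the strain-to-parent mapping flips:
#' `cross_direction = "PxB"` swaps the maternal/paternal interpretation of
#' the SNP table, which is oriented for the first-named strain as mother
#' (`"BxP"`).
#'
#' @param reads Tibble of filtered reads with `read_id`, `chrom`, `start`,
#'   `end` and list-columns `snp_pos` (integer positions) and `snp_obs`
#'   (observed bases).
#' @param snps SNP table with `chrom`, `pos`, `mat_base`, `pat_base`
#'   (distinct bases, unique positions per chromosome).
#' @param min_informative Minimum informative SNPs for an allele call.
#' @param cross_direction `"BxP"` (SNP table orientation) or `"PxB"`.
#' @return A tibble `read_id`, `verdict`, `n_snps_covered`, `n_maternal`,
#'   `n_paternal`.
#' @export
assign_alleles <- function(reads, snps, min_informative = 1,
                           cross_direction = c("BxP", "PxB")) {
  cross_direction <- match.arg(cross_direction)
  if (any(snps$mat_base == snps$pat_base)) {
    stop("SNP table contains entries with identical parental bases",
         call. = FALSE)
  }
  if (anyDuplicated(snps[, c("chrom", "pos")]) > 0) {
    stop("SNP table contains duplicated positions", call. = FALSE)
  }
  mat_base <- if (cross_direction == "BxP") snps$mat_base else snps$pat_base
  pat_base <- if (cross_direction == "BxP") snps$pat_base else snps$mat_base
  snp_key <- paste(snps$chrom, snps$pos)
  mat_lut <- stats::setNames(mat_base, snp_key)
  pat_lut <- stats::setNames(pat_base, snp_key)

  score <- function(chrom, pos, obs) {
    if (length(pos) == 0) return(c(0L, 0L, 0L))
    key <- paste(chrom, pos)
    m <- mat_lut[key]
    p <- pat_lut[key]
    known <- !is.na(m)
    c(sum(known), sum(known & obs == m), sum(known & obs == p))
  }
  tallies <- t(mapply(score, reads$chrom, reads$snp_pos, reads$snp_obs,
                      SIMPLIFY = TRUE, USE.NAMES = FALSE))
  if (nrow(reads) == 0) {
    tallies <- matrix(integer(0), ncol = 3)
  }
  n_cov <- tallies[, 1]
  n_mat <- tallies[, 2]
  n_pat <- tallies[, 3]
  verdict <- dplyr::case_when(
    n_mat > 0 & n_pat > 0 ~ "conflicting",
    n_mat >= min_informative & n_pat == 0 ~ "maternal",
    n_pat >= min_informative & n_mat == 0 ~ "paternal",
    .default = "unassigned"
  )
  tibble::tibble(
    read_id = reads$read_id,
    verdict = verdict,
    n_snps_covered = as.integer(n_cov),
    n_maternal = as.integer(n_mat),
    n_paternal = as.integer(n_pat)
  )
}

#' Count allele-assigned reads over features
#'
#' Attributes each read to the feature containing its start position (BED
#' convention, half-open) and tallies maternal, paternal, unassigned and
#' conflicting reads per feature. The four verdicts partition the input:
#' their grand totals always sum to the number of reads supplied.
#'
#' @param assignments Output of [assign_alleles()].
#' @param reads The read tibble the assignments were computed from.
#' @param features Tibble of non-overlapping intervals with `chrom`,
#'   `start`, `end` and a `feature_id` (or `locus_id`/`gene_id`) column.
#' @return A tibble with one row per feature: `feature_id`, `maternal`,
#'   `paternal`, `unassigned`, `conflicting`. Reads outside every feature
#'   are tallied in the attribute `unattributed` (named verdict counts).
#' @export
count_allelic <- function(assignments, reads, features) {
  check_intervals(features, "features")
  idcol <- intersect(c("feature_id", "locus_id", "gene_id"), names(features))[1]
  if (is.na(idcol)) stop("features need an id column", call. = FALSE)

  joined <- dplyr::inner_join(
    assignments, reads[, c("read_id", "chrom", "start")], by = "read_id")

  feat <- features |>
    dplyr::transmute(feature_id = .data[[idcol]], .data$chrom,
                     fstart = .data$start, fend = .data$end)
  hits <- dplyr::inner_join(joined, feat, by = "chrom",
                            relationship = "many-to-many") |>
    dplyr::filter(.data$start >= .data$fstart, .data$start < .data$fend)

  verdicts <- c("maternal", "paternal", "unassigned", "conflicting")
  counts <- hits |>
    dplyr::count(.data$feature_id, .data$verdict) |>
    tidyr::pivot_wider(names_from = "verdict", values_from = "n",
                       values_fill = 0L)
  for (v in setdiff(verdicts, names(counts))) counts[[v]] <- 0L
  out <- tibble::tibble(feature_id = feat$feature_id) |>
    dplyr::left_join(counts, by = "feature_id") |>
    dplyr::mutate(dplyr::across(dplyr::all_of(verdicts),
                                ~ tidyr::replace_na(.x, 0L))) |>
    dplyr::select(dplyr::all_of(c("feature_id", verdicts)))

  outside <- joined[!joined$read_id %in% hits$read_id, ]
  attr(out, "unattributed") <- table(factor(outside$verdict, levels = verdicts))
  out
}
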