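# Readers and writers for the plain-text interchange formats: BED intervals,
# TSV count matrices, bedGraph-like methylation, VCF-like SNP tables and
# GTF-like gene tables. All tab-separated, UTF-8, LF-terminated; coordinates
# BED-style 0-based half-open throughout.

read_tsv_quiet <- function(path, col_types) {
  readr::read_tsv(path, col_types = col_types, progress = FALSE)
}

write_tsv_lf <- function(x, path) {
  readr::write_tsv(x, path, eol = "\n", progress = FALSE)
}

#' Read and write BED interval files
#'
#' Three-or-more-column BED, 0-based half-open. Malformed lines (missing
#' columns, non-numeric coordinates, `start >= end`) are reported with
#' their line numbers.
#'
#' @param path File path.
#' @return `read_bed()`: a tibble `chrom`, `start`, `end` (plus a `name`
#'   column when a 4th BED column is present).
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  bad <- which(n_col < 3)
  if (length(bad) > 0) {
    stop(sprintf("BED parse error: fewer than 3 columns at line(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    stop(sprintf("BED parse error: non-numeric coordinates at line(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  bad <- which(start >= end)
  if (length(bad) > 0) {
    stop(sprintf("BED parse error: start >= end at line(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  out <- tibble::tibble(chrom = vapply(fields, `[[`, "", 1),
                        start = start, end = end)
  if (all(n_col >= 4)) out$name <- vapply(fields, `[[`, "", 4)
  out
}

#' @rdname read_bed
#' @param intervals Tibble with `chrom`, `start`, `end` (and optional
#'   `name`).
#' @export
write_bed <- function(intervals, path) {
  check_intervals(intervals)
  cols <- intersect(c("chrom", "start", "end", "name"), names(intervals))
  readr::write_tsv(intervals[, cols], path, col_names = FALSE, eol = "\n",
                   progress = FALSE)
  invisible(path)
}

#' Read a VCF-like strain SNP table
#'
#' Tab-separated `chrom`, `pos`, `mat_base`, `pat_base`. Rows with
#' identical parental bases or duplicated positions are rejected.
#'
#' @param path File path.
#' @return A validated SNP tibble.
#' @export
read_snp_table <- function(path) {
  x <- read_tsv_quiet(path, readr::cols(chrom = "c", pos = "i",
                                        mat_base = "c", pat_base = "c"))
  if (any(x$mat_base == x$pat_base)) {
    stop("SNP table: identical parental bases in some rows", call. = FALSE)
  }
  if (anyDuplicated(x[, c("chrom", "pos")]) > 0) {
    stop("SNP table: duplicated positions", call. = FALSE)
  }
  x
}

#' Read a bedGraph-like per-CpG methylation table
#'
#' Tab-separated `chrom`, `start`, `end`, `level`, `coverage`; levels
#' outside `[0, 1]` or negative coverage are rejected.
#'
#' @param path File path.
#' @return A validated methylation tibble.
#' @export
read_methylation <- function(path) {
  x <- read_tsv_quiet(path, readr::cols(chrom = "c", start = "i", end = "i",
                                        level = "d", coverage = "i"))
  if (any(x$level < 0 | x$level > 1)) {
    stop("methylation table: level outside [0, 1]", call. = FALSE)
  }
  if (any(x$coverage < 0)) {
    stop("methylation table: negative coverage", call. = FALSE)
  }
  x
}

#' Read a long count table
#'
#' Tab-separated with at least `gene_id` (or `locus_id`), `sample`,
#' `count`; negative counts are rejected.
#'
#' @param path File path.
#' @return A validated count tibble.
#' @export
read_counts <- function(path) {
  x <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  if (!"count" %in% names(x)) stop("count table needs a `count` column",
                                   call. = FALSE)
  if (any(x$count < 0)) stop("count table: negative counts", call. = FALSE)
  x
}

#' Read a GTF-like gene model table
#'
#' Tab-separated `gene_id`, `chrom`, `tss`, `strand`, `exonic_length`.
#'
#' @param path File path.
#' @return A validated gene tibble (duplicate `gene_id` rejected).
#' @export
read_genes <- function(path) {
  x <- read_tsv_quiet(path, readr::cols(gene_id = "c", chrom = "c",
                                        tss = "i", strand = "c",
                                        exonic_length = "i"))
  if (anyDuplicated(x$gene_id) > 0) {
    stop("gene table: duplicated gene_id", call. = FALSE)
  }
  x
}
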