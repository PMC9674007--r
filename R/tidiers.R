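#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-locus records of a cascade
#'
#' @param x An `imprint_cascade` from [run_cascade()].
#' @param ... Unused.
#' @return The per-locus record tibble: one row per input locus with its
#'   filter flags, the removing filter (or `"survived"`) and the assigned
#'   gene.
#' @export
tidy.imprint_cascade <- function(x, ...) x$records

#' One-row summary of a cascade
#'
#' @param x An `imprint_cascade`.
#' @param ... Unused.
#' @return A one-row tibble: survivor count after each filter and the
#'   number of candidate genes.
#' @export
glance.imprint_cascade <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$counts, names_from = "stage",
                             values_from = "survivors")
  names(wide) <- paste0("n_", names(wide))
  dplyr::mutate(wide, n_candidate_genes = nrow(x$candidates))
}

#' Tidy a pipeline run into its per-locus call table
#'
#' @param x An `imprintscan_run` from [run_pipeline()].
#' @param ... Unused.
#' @return Per-locus tibble joining the allelic DHS call, methylation
#'   class, cascade provenance and assigned gene.
#' @export
tidy.imprintscan_run <- function(x, ...) {
  x$cascade$records |>
    dplyr::left_join(x$meth[, c("locus_id", "meth_mean")], by = "locus_id")
}

#' One-row summary of a pipeline run
#'
#' @param x An `imprintscan_run`.
#' @param ... Unused.
#' @return A one-row tibble with locus, read, cascade-survivor, candidate
#'   and expression-bias counts.
#' @export
glance.imprintscan_run <- function(x, ...) {
  g <- glance(x$cascade)
  dplyr::mutate(
    g,
    n_loci = x$manifest$n_loci,
    n_reads_filtered = x$manifest$n_reads_filtered,
    n_candidates_biased = sum(
      x$expression_bias$candidate &
        x$expression_bias$bias %in% c("biased", "highly biased")),
    n_rescued = if (is.null(x$rescue)) NA_integer_ else
      sum(x$rescue$rescue == "rescued"),
    n_derepressed = if (is.null(x$derepression)) NA_integer_ else
      sum(x$derepression$derepressed, na.rm = TRUE)
  )
}
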