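#' Nearest gene (by TSS) for each interval
#'
#' Associates each interval with the gene whose TSS is closest: distance 0
#' when the TSS falls inside the half-open interval, otherwise the gap in
#' bp from the nearer interval edge. Only genes on the same chromosome are
#' considered (no gene there gives `NA`). Ties are broken by the
#' lexicographically smaller `gene_id`, so the association is
#' deterministic.
#'
#' @param intervals Tibble `chrom`, `start`, `end` (plus id columns,
#'   carried through).
#' @param gene_models Tibble `gene_id`, `chrom`, `tss`.
#' @return `intervals` with `gene_id` and `tss_distance` columns.
#' @export
nearest_gene <- function(intervals, gene_models) {
  check_intervals(intervals)
  if (nrow(gene_models) == 0) stop("empty gene model set", call. = FALSE)
  res <- lapply(seq_len(nrow(intervals)), function(i) {
    g <- gene_models[gene_models$chrom == intervals$chrom[i], ]
    if (nrow(g) == 0) {
      return(tibble::tibble(gene_id = NA_character_,
                            tss_distance = NA_real_))
    }
    d <- ifelse(g$tss >= intervals$start[i] & g$tss < intervals$end[i], 0,
                pmin(abs(g$tss - intervals$start[i]),
                     abs(g$tss - (intervals$end[i] - 1))))
    best <- which(d == min(d))
    best <- best[order(g$gene_id[best])][1]
    tibble::tibble(gene_id = g$gene_id[best], tss_distance = d[best])
  })
  dplyr::bind_cols(intervals, dplyr::bind_rows(res))
}

cascade_filters <- c("ag_dhs", "hypomethylated", "icm_mat_k27",
                     "zygote_mat_k27")

#' Run the H3K27me3-dependent imprinting discovery cascade
#'
#' The integration step: starting from the allelic DHS calls of
#' uniparental morulae, loci are passed through four ordered filters —
#' (1) AG-specific DHS (open only when the paternal genome is present),
#' (2) oocyte DNA-hypomethylated class (removing canonical, gDMR-driven
#' loci), (3) maternal allele-biased H3K27me3 in blastocyst ICM
#' (RPM > 0.5, FC > 2), and (4) maternal allele-specific H3K27me3 already
#' present in zygotes (RPM > 0.5, FC > 4, showing the mark is inherited
#' from the oocyte) — then surviving DHSs are associated with their
#' nearest genes and deduplicated into the candidate set of putative
#' H3K27me3-dependent imprinted genes. Every input locus is retained in
#' the record table with the first filter that removed it (or
#' `"survived"`), so survivor counts are monotone non-increasing along the
#' cascade and the provenance buckets partition the input.
#'
#' @param dhs_calls Output of [classify_allelic_dhs()] on AG/GG morula
#'   data, keyed by `locus_id` (AG-specific = `"paternal-specific"`).
#' @param meth Tibble `locus_id`, `meth_class` (from
#'   [methylation_class()]).
#' @param icm_chip,zygote_chip Tibbles `locus_id`, `mat_rpm`, `pat_rpm`
#'   at the two stages.
#' @param gene_models Tibble `gene_id`, `chrom`, `tss`.
#' @param rpm_min ChIP maternal RPM gate (default 0.5).
#' @return An object of class `imprint_cascade`: a list with `records`
#'   (per-locus flags, `removed_at`, assigned gene), `candidates`
#'   (per-gene tibble with supporting DHS ids) and `counts` (survivors
#'   after each filter).
#' @export
run_cascade <- function(dhs_calls, meth, icm_chip, zygote_chip, gene_models,
                        rpm_min = 0.5) {
  key_missing <- function(tbl, what) {
    miss <- setdiff(dhs_calls$locus_id, tbl$locus_id)
    if (length(miss) > 0) {
      stop(sprintf("%s table is missing locus id(s): %s", what,
                   paste(utils::head(miss, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  if (nrow(dhs_calls) > 0) {
    key_missing(meth, "methylation")
    key_missing(icm_chip, "ICM ChIP")
    key_missing(zygote_chip, "zygote ChIP")
  }

  records <- dhs_calls |>
    dplyr::left_join(meth[, c("locus_id", "meth_class")], by = "locus_id") |>
    dplyr::left_join(
      dplyr::transmute(icm_chip, .data$locus_id,
                       icm_mat_rpm = .data$mat_rpm,
                       icm_pat_rpm = .data$pat_rpm),
      by = "locus_id") |>
    dplyr::left_join(
      dplyr::transmute(zygote_chip, .data$locus_id,
                       zyg_mat_rpm = .data$mat_rpm,
                       zyg_pat_rpm = .data$pat_rpm),
      by = "locus_id") |>
    dplyr::mutate(
      is_ag_dhs = .data$class == "paternal-specific",
      is_hypomethylated = .data$meth_class == "hypo",
      icm_mat_k27 = chip_allelic_bias(.data$icm_mat_rpm, .data$icm_pat_rpm,
                                      stage = "icm", rpm_min = rpm_min),
      zygote_mat_k27 = chip_allelic_bias(.data$zyg_mat_rpm, .data$zyg_pat_rpm,
                                         stage = "zygote", rpm_min = rpm_min),
      removed_at = dplyr::case_when(
        !is_ag_dhs ~ "ag_dhs",
        !is_hypomethylated ~ "hypomethylated",
        !icm_mat_k27 ~ "icm_mat_k27",
        !zygote_mat_k27 ~ "zygote_mat_k27",
        .default = "survived"
      )
    )

  survivors <- records[records$removed_at == "survived", ]
  if (nrow(survivors) > 0) {
    survivors <- nearest_gene(survivors, gene_models)
    candidates <- survivors |>
      dplyr::filter(!is.na(.data$gene_id)) |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(n_dhs = dplyr::n(),
                       dhs_ids = list(sort(.data$locus_id)),
                       .groups = "drop")
    records <- records |>
      dplyr::left_join(survivors[, c("locus_id", "gene_id", "tss_distance")],
                       by = "locus_id")
  } else {
    candidates <- tibble::tibble(gene_id = character(), n_dhs = integer(),
                                 dhs_ids = list())
    records$gene_id <- NA_character_
    records$tss_distance <- NA_real_
  }

  stages <- c("input", cascade_filters)
  remaining <- nrow(records)
  counts <- integer(length(stages))
  counts[1] <- remaining
  for (k in seq_along(cascade_filters)) {
    remaining <- remaining -
      sum(records$removed_at == cascade_filters[k])
    counts[k + 1] <- remaining
  }
  structure(
    list(records = records,
         candidates = candidates,
         counts = tibble::tibble(stage = stages, survivors = counts)),
    class = "imprint_cascade"
  )
}

#' @export
print.imprint_cascade <- function(x, ...) {
  cat("H3K27me3-dependent imprinting cascade\n")
  cat(sprintf("  %d loci -> %s survivors -> %d candidate genes\n",
              x$counts$survivors[1],
              paste(x$counts$survivors[-1], collapse = " -> "),
              nrow(x$candidates)))
  invisible(x)
}

#' Label the imprinting mechanism of genes
#'
#' `non-canonical` for cascade candidates (maternal-H3K27me3-dependent);
#' `canonical` for genes called imprinted whose locus overlaps or is
#' associated with a germline DMR and which are not cascade candidates;
#' `unknown` otherwise.
#'
#' @param genes Tibble with `gene_id`, an imprint `status` column (values
#'   `"PEG"`/`"MEG"` count as imprinted) and a `gdmr_association` column
#'   (from [neighborhood_gdmr_association()], joined per gene).
#' @param cascade An `imprint_cascade` (or a character vector of candidate
#'   gene ids).
#' @return `genes` with a `mechanism` column.
#' @export
label_mechanism <- function(genes, cascade) {
  cand <- if (inherits(cascade, "imprint_cascade")) {
    cascade$candidates$gene_id
  } else {
    as.character(cascade)
  }
  genes |>
    dplyr::mutate(mechanism = dplyr::case_when(
      .data$gene_id %in% cand ~ "non-canonical",
      .data$status %in% c("PEG", "MEG") &
        .data$gdmr_association %in% c("overlapping", "associated") ~ "canonical",
      .default = "unknown"
    ))
}

lineage_stages <- c("2cell", "morula", "blastocyst_ICM", "blastocyst_TE",
                    "E6.5_EPI", "E6.5_VE", "E6.5_EXE", "E9.5_placenta")

#' Summarise per-gene imprinting trajectories across lineages
#'
#' Orders each gene's per-stage imprint statuses along development and
#' assigns a summary label: `maintained` when the gene is still imprinted
#' in the post-implantation epiblast; `extraembryonic-maintained` when it
#' is imprinted in extra-embryonic ectoderm or placenta but not in the
#' epiblast; `transient` when imprinting is confined to earlier stages;
#' `N.D.` when no stage could be determined.
#'
#' @param calls Tibble `gene_id`, `stage` (values among `"2cell"`,
#'   `"morula"`, `"blastocyst_ICM"`, `"blastocyst_TE"`, `"E6.5_EPI"`,
#'   `"E6.5_VE"`, `"E6.5_EXE"`, `"E9.5_placenta"`), `status` (`"PEG"`,
#'   `"MEG"`, `"not imprinted"`, `"N.D."`).
#' @return One row per gene: the per-stage statuses (wide) and a
#'   `trajectory` label.
#' @export
lineage_dynamics <- function(calls) {
  bad <- setdiff(unique(calls$stage), lineage_stages)
  if (length(bad) > 0) {
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  imprinted <- function(s) !is.na(s) & s %in% c("PEG", "MEG")
  wide <- calls |>
    dplyr::mutate(stage = factor(.data$stage, levels = lineage_stages)) |>
    tidyr::pivot_wider(id_cols = "gene_id", names_from = "stage",
                       values_from = "status",
                       names_expand = TRUE)
  status_cols <- intersect(lineage_stages, names(wide))
  wide |>
    dplyr::rowwise() |>
    dplyr::mutate(trajectory = {
      s <- stats::setNames(
        dplyr::c_across(dplyr::all_of(status_cols)), status_cols)
      if (all(is.na(s) | s == "N.D.")) "N.D."
      else if (imprinted(s["E6.5_EPI"])) "maintained"
      else if (imprinted(s["E6.5_EXE"]) || imprinted(s["E9.5_placenta"])) {
        "extraembryonic-maintained"
      } else "transient"
    }) |>
    dplyr::ungroup()
}
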