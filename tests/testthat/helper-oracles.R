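# Naive, independently written threshold evaluators used as oracles.
# These deliberately spell every rule out long-hand, one condition at a
# time, and share no code with the package implementation.

oracle_dhs_call <- function(mat, pat, sex = FALSE,
                            mean_min = 2, rep_min = 1, fc_min = 4) {
  if (sex) return("excluded")
  mat_mean <- sum(mat) / length(mat)
  pat_mean <- sum(pat) / length(pat)
  pat_ok <- pat_mean > mean_min
  for (v in pat) if (v <= rep_min) pat_ok <- FALSE
  mat_ok <- mat_mean > mean_min
  for (v in mat) if (v <= rep_min) mat_ok <- FALSE
  # fold changes, infinity when the other allele has zero mean
  if (mat_mean == 0) fc_p <- if (pat_mean > 0) Inf else NA else fc_p <- pat_mean / mat_mean
  if (pat_mean == 0) fc_m <- if (mat_mean > 0) Inf else NA else fc_m <- mat_mean / pat_mean
  if (pat_ok && !is.na(fc_p) && fc_p > fc_min) return("paternal-specific")
  if (mat_ok && !is.na(fc_m) && fc_m > fc_min) return("maternal-specific")
  if (pat_ok && mat_ok && fc_p <= fc_min && fc_m <= fc_min) return("bi-allelic")
  "unclassified"
}

oracle_gdmr <- function(oo, sp) {
  if (is.na(oo) || is.na(sp)) return(NA_character_)
  if (oo > 0.8) { if (sp < 0.2) return("oocyte gDMR") }
  if (sp > 0.8) { if (oo < 0.2) return("sperm gDMR") }
  "none"
}

oracle_meth_class <- function(oo) {
  if (is.na(oo)) return("undefined")
  if (oo >= 0 && oo <= 0.2) return("hypo")
  if (oo >= 0.8 && oo <= 1) return("hyper")
  "intermediate"
}

oracle_chip_bias <- function(mat, pat, stage) {
  cut <- if (stage == "icm") 2 else 4
  if (!(mat > 0.5)) return(FALSE)
  if (pat == 0) return(mat > 0)
  mat / pat > cut
}

oracle_nascent <- function(fdr, mean_fpkm, ama_fpkm) {
  if (!(fdr < 0.05)) return(FALSE)
  if (!(mean_fpkm > 2)) return(FALSE)
  if (ama_fpkm == 0) return(mean_fpkm > 0)
  mean_fpkm / ama_fpkm > 2
}

oracle_deg <- function(ag, gg, ama) {
  a <- ag - ama; if (a < 0) a <- 0
  g <- gg - ama; if (g < 0) g <- 0
  if (a == 0 && g == 0) return("none")
  if (g == 0) return(if (a > 0) "AG-specific" else "none")
  if (a == 0) return(if (g > 0) "GG-specific" else "none")
  if (a / g > 10) return("AG-specific")
  if (g / a > 10) return("GG-specific")
  "none"
}

oracle_imprint <- function(bm, bp, pm, pp, min_reads = 20) {
  if (bm + bp < min_reads || pm + pp < min_reads) return("N.D.")
  r <- function(x, y) if (y == 0) (if (x > 0) Inf else NA) else x / y
  f1 <- r(bp, bm); f2 <- r(pp, pm)
  g1 <- r(bm, bp); g2 <- r(pm, pp)
  if (!is.na(f1) && !is.na(f2) && f1 > 2 && f2 > 2) return("PEG")
  if (!is.na(g1) && !is.na(g2) && g1 > 2 && g2 > 2) return("MEG")
  "not imprinted"
}

# Long-hand Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# Position-set union oracle for interval merging (half-open coordinates).
oracle_merge <- function(df) {
  out <- list()
  for (ch in sort(unique(df$chrom))) {
    d <- df[df$chrom == ch, ]
    span <- rep(FALSE, max(d$end) + 1)
    for (i in seq_len(nrow(d))) span[(d$start[i] + 1):d$end[i]] <- TRUE
    r <- rle(span)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values
    out[[ch]] <- tibble::tibble(chrom = ch, start = starts[keep] - 1L,
                                end = ends[keep])
  }
  dplyr::bind_rows(out)
}

small_config <- function(...) {
  generator_config(n_autosomal_loci = 60, n_sex_loci = 5, n_replicates = 3,
                   seed = 42L, ...)
}
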