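# Internal helpers: named RNG substreams and small validators.

# Deterministic string hash -> non-negative integer < 2^31 - 1.
# Horner scheme over UTF-8 code points; stable across platforms.
hash_key <- function(key) {
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 31 + cp) %% 2147483647
  as.integer(h)
}

# Derive a child seed from a master seed and a substream name so that
# regenerating one table never perturbs the draws of another.
derive_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  as.integer((as.double(seed) %% 2147483647 + hash_key(key)) %% 2147483647)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_substream <- function(seed, key, code) {
  withr::with_seed(derive_seed(seed, key), code)
}

# NB draws parameterised by mean and dispersion alpha (var = mu + alpha mu^2).
# alpha = 0 is the deterministic limit: expected counts, rounded.
rnb <- function(n, mu, alpha) {
  if (alpha <= 0) return(round(rep_len(mu, n)))
  stats::rnbinom(n, mu = mu, size = 1 / alpha)
}

# Gamma draws with given mean and coefficient of variation; cv = 0 is exact.
rgamma_cv <- function(n, mean, cv) {
  out <- rep_len(mean, n)
  pos <- out > 0
  if (cv <= 0 || !any(pos)) return(out)
  shape <- 1 / cv^2
  out[pos] <- stats::rgamma(sum(pos), shape = shape, rate = shape / out[pos])
  out
}

# Beta draws with given mean and sd; sd = 0 is exact. Means at 0 or 1 are
# returned as-is (degenerate beta).
rbeta_ms <- function(n, mean, sd) {
  out <- rep_len(mean, n)
  if (sd <= 0) return(out)
  inner <- out > 0 & out < 1
  if (!any(inner)) return(out)
  m <- out[inner]
  v <- pmin(sd^2, m * (1 - m) * 0.99)
  k <- m * (1 - m) / v - 1
  out[inner] <- stats::rbeta(sum(inner), m * k, (1 - m) * k)
  out
}

stopifnot_scalar_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single fraction in [0, 1]", name), call. = FALSE)
  }
}

stopifnot_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
}

check_intervals <- function(x, what = "intervals") {
  needed <- c("chrom", "start", "end")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    stop(sprintf("%s must have columns %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad <- which(x$start >= x$end)
  if (length(bad) > 0) {
    stop(sprintf("%s: start >= end at row(s) %s", what,
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# Half-open interval overlap test, vectorised over the first set.
overlaps_any <- function(chrom, start, end, set) {
  if (nrow(set) == 0) return(rep(FALSE, length(chrom)))
  vapply(seq_along(chrom), function(i) {
    any(set$chrom == chrom[i] & set$start < end[i] & set$end > start[i])
  }, logical(1))
}
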