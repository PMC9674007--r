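---
title: "Detecting H3K27me3-dependent genomic imprinting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting H3K27me3-dependent genomic imprinting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintscan)
library(dplyr)
```

## The biological question

Genomic imprinting — parent-of-origin-specific gene expression — was long
equated with germline differentially methylated regions (gDMRs): loci
methylated in one gamete (classically the oocyte) and unmethylated in the
other, whose methylation survives post-fertilisation reprogramming and
silences one parental allele. A second, DNA-methylation-independent
mechanism exists in early mouse embryos: broad maternal H3K27me3
(Polycomb) domains laid down in the oocyte keep the *maternal* allele of
certain genes closed and silent even though the locus is unmethylated in
both gametes. `imprintscan` implements the computational procedure for
discovering such "non-canonical" imprinted genes from allele-resolved
chromatin accessibility (low-input DNase I hypersensitivity), nascent
transcription, gamete methylomes and allelic H3K27me3 ChIP signal — plus
a synthetic multi-omic generator that plants both kinds of imprinted loci
so the whole cascade can be validated against known ground truth without
any external data.

The experimental designs the package models:

* **Parental-allele accessibility.** Maternal and paternal pronuclei of
  zygotes profiled separately; at later stages, androgenetic (AG, two
  paternal genomes) versus gynogenetic/parthenogenetic (GG/PG, two
  maternal genomes) embryos. An "AG-specific DHS" is open only when a
  paternal genome is present — the accessibility signature of a
  maternally silenced locus.
* **Nascent transcription at zygotic genome activation.** 2-cell embryos
  carry a large maternal stored-transcript pool; α-amanitin-treated
  embryos (transcription blocked) contain *only* that store, so
  store-subtraction and spike-in normalisation separate new transcription
  from inheritance.
* **Demethylase perturbation.** Injecting mRNA of the H3K27me3
  demethylase Kdm6b (versus its catalytic mutant) erases the maternal
  mark; loci silenced *by* the mark re-open ("rescue") and their genes
  re-express ("derepression"), while DNA-methylation-protected loci are
  untouched.
* **Reciprocal hybrid crosses.** Strain SNPs let reads be assigned to
  parental alleles; requiring an allelic bias in *both* cross directions
  separates parent-of-origin effects from strain effects.

## The decision rules

All rules are strict inequalities exactly as stated, and every threshold
lives in `pipeline_config()` with its default recorded beside any
override.

**Allele-specific DHS** (`classify_allelic_dhs()`): a biased allele needs
mean RPKM > 2, RPKM > 1 in *every* replicate, and a mean fold change > 4
over the other allele. RPKM is reads per kb of DHS per million mapped
reads. We define *bi-allelic* as both alleles passing mean > 2 and
min > 1 with neither direction exceeding fold change 4; the source
criteria name only the allele-specific cutoffs, so the bi-allelic
definition is this package's declared convention. Fold changes with a
zero denominator are `+Inf` (they pass); no pseudocount is added, because
a pseudocount would silently change calls near the boundary. Sex
chromosomes are excluded outright (their copy number differs between
pronuclei and between AG/GG embryos).

**Most reliable subset** (`reliable_subset()`): paternal-specific DHSs
additionally need paternal RPKM > 1 in every replicate of the
microinjected-zygote paternal pronuclei.

**Rescue** (`rescue_call()`): a reliable Ps-DHS "became bi-allelic" under
the demethylase when the WT arm shows maternal mean RPKM > 1 with
paternal/maternal fold change ≤ 2 while the catalytic-mutant arm still
satisfies the paternal-specific rule. The original report gives rescue
counts but not the underlying cutoffs; this rule is a configurable
convention (`rescue_wt_mat_min`, `rescue_wt_fc_max`) and is flagged as
such.

**Methylation** (`classify_gdmr()`, `methylation_class()`): an oocyte
gDMR has > 80% oocyte and < 20% sperm methylation (strict, as printed);
the hypo/hypermethylated *classes* are the closed intervals 0–20% and
80–100% (a locus at exactly 20% is hypomethylated). The two rules differ
deliberately because their sources print them differently. Interval
methylation is the coverage-weighted CpG mean over the interval ± 2 kb
(`extend_bp`, clamped at zero) — the extension recruits nearby CpGs so
short DHSs get usable bisulfite coverage; we apply it wherever interval
methylation is computed and expose the knob. gDMR neighbourhood
association tiles ± 100 kb flanks with whole 1-kb bins.

**Allelic H3K27me3** (`chip_allelic_bias()`): maternal RPM > 0.5 (signal
over the DHS ± 1 kb; RPM deliberately has no length normalisation) and
maternal/paternal fold change > 2 in blastocyst ICM or > 4 in zygotes.
The zygote criterion nests inside the ICM one.

**Expression**: nascent genes need exact-NB FDR < 0.05 against
α-amanitin, mean FPKM > 2 and fold change > 2; allelic DEGs need a > 10
fold change after store subtraction (negatives clamped to 0 — negative
nascent expression is non-physical); morula AG/GG bias uses
FPKM > 0.5 for "expressed", FC > 2 for biased and FC > 8 for highly
biased; reciprocal-cross imprint calls need FC > 2 in both crosses with
≥ 20 SNP reads per cross (10 in the injection experiments — a per-call
parameter, never hard-coded).

**The cascade** (`run_cascade()`): ordered filters (1) AG-specific DHS,
(2) oocyte-hypomethylated, (3) ICM maternal H3K27me3 bias, (4) zygotic
maternal H3K27me3 bias, then nearest-gene assignment (nearest TSS,
distance 0 if the TSS lies inside the interval, ties broken by the
lexicographically smaller gene id) and deduplication to a candidate gene
set. Every locus records the first filter that removed it, so survivor
counts are monotone and the provenance buckets partition the input.

## ERCC anchoring and the exact NB test

Size factors come from a median-of-ratios estimator over spike-in rows
only (`size_factors_ercc()`): endogenous genes never enter the estimator,
so a genuine global shift in transcription — the very quantity an
α-amanitin comparison measures — is preserved. For the same reason
`fpkm()` uses a *common* per-million denominator (the mean of the
per-sample normalised totals) rather than each sample's own total, which
would re-normalise that global difference away.

`nb_test()` is a conditioned negative-binomial exact test: per-sample
counts are modelled NB with common mean after size-factor normalisation
and common dispersion $\alpha$ (variance $\mu + \alpha\mu^2$); the
two-sided p-value sums the probabilities of all allocations of the
observed grand total between the two group sums that are no more likely
than the observed allocation. Group sums are treated as NB with matched
mean and variance ($\mathrm{var}(K_A) = \mu_A + \alpha q_0^2 \sum_j
s_j^2$); when the estimated variance does not exceed the mean the Poisson
limit is used. All-zero genes return $p = 1$ by convention.

Dispersion handling was a genuinely open design point. For a single gene,
`nb_test()` uses a floored method-of-moments estimate pooled across both
groups. For gene tables, `nb_test_genes()` fits the mean–dispersion trend
$\alpha(\mu) = a_0 + a_1/\mu$ across genes and uses the *fitted* value
for every gene (fit-only sharing). We also implemented the alternative of
taking the per-gene maximum against the trend and measured both on a
2,000-gene NB null ($\mu = 100$, $\alpha = 0.1$, 3 + 3 samples): the
maximum rule rejects at 0.012–0.027 at a nominal 0.05 — markedly
conservative — while fit-only sharing rejects at 0.049–0.053 and keeps
power increasing with effect size. With the two-to-three replicates
typical of embryo experiments the per-gene estimate carries almost no
information, so the trend is the better-calibrated choice and is the
default. The test suite checks the type-I error, a power ladder at three
effect sizes, and agreement of the p-value with an independent exhaustive
tail-sum enumeration on a fixed small case.

## The synthetic-data generator

`generator_config()` + `simulate_dataset()` emulate the full study on a
desk-scale genome (five 2-Mb autosomes plus chrX; uniformly spaced
600-bp loci, 0-based half-open coordinates throughout). Three planted
locus classes drive every assay consistently:

| class | oocyte meth | sperm meth | maternal K27 (RPM) | accessibility | expression |
|---|---|---|---|---|---|
| none | 0.10 | 0.10 | 0.10 | both open | both alleles |
| canonical | 0.90 | 0.05 | 0.10 | maternal closed | paternal |
| non-canonical | 0.05 | 0.05 | 2.00 | maternal closed | paternal |

Counts are negative-binomial with variance $\mu + \alpha\mu^2$
(`nb_dispersion`, default 0.05; 0 gives the deterministic expected-count
limit — NB is the field's standard count model and matches the test
downstream). Open alleles draw around `mean_depth` (200), closed alleles
around 2% of it. Methylation adds per-CpG beta noise (sd 0.05), ChIP RPM
gamma noise (CV 0.2), and expression libraries draw log-normal true size
factors (sd 0.3) that scale genes and spike-ins alike and are recorded in
the output for recovery checks. The maternal store is a gene-specific
log-normal level (median 20 FPKM-scale) shared by AG, GG and α-amanitin
2-cell samples, which makes the store-subtraction step meaningfully
testable. No noise or effect magnitudes are stated in the source for any
assay; these defaults were chosen once as values a practitioner would
call realistic for the respective assays, and are calibration knobs, not
claims.

Kdm6b erasure acts per locus (a Bernoulli draw with probability
`kdm6b_efficiency`, the simplest model consistent with a bulk readout)
and the draw is *shared* across the accessibility, expression and ChIP
arms, so a rescued locus re-opens, re-expresses and loses maternal ChIP
signal coherently. Each emitted table uses an independent, named seed
substream derived from one master seed, so the WT and mutant injection
arms share their base randomness: with efficiency 0 the WT arm is
bit-identical to the mutant arm, and canonical loci are bit-identical
between arms at any efficiency — the perturbation is provably local.

What the generator does *not* emulate: raw sequence strings, base
qualities, bisulfite conversion chemistry, alignment and mapping-bias
artifacts, gapped reads, indel SNPs, copy-number differences, or
inter-embryo variability beyond NB dispersion. Passing the planted-truth
tests therefore demonstrates that the decision logic is implemented
correctly and is recoverable under calibrated noise — not that the
thresholds themselves are optimal for real sequencing data.

## A worked run

```{r pipeline}
cfg <- generator_config(n_autosomal_loci = 150, n_sex_loci = 5,
                        frac_canonical = 0.1, frac_noncanonical = 0.1,
                        seed = 7L)
bundle <- simulate_dataset(cfg)
run <- run_pipeline(bundle)
run
glance(run)
```

The cascade funnel and the allelic-DHS scatter:

```{r plots, fig.width = 6, fig.height = 3.5}
ggplot2::autoplot(run$cascade)
plot_allelic_dhs(run$dhs_calls)
```

Candidate recovery against the planted truth:

```{r recovery}
truth_nc <- bundle$truth$gene_id[bundle$truth$imprint_class == "non-canonical"]
cand <- run$candidates$gene_id
c(precision = mean(cand %in% truth_nc), recall = mean(truth_nc %in% cand))
```

## Numerical conventions and degenerate inputs

* Coordinates are BED-style 0-based half-open everywhere; book-ended
  intervals merge (as `bedtools merge` would).
* Duplicate reads collapse to one survivor per (chrom, start,
  orientation); the lexicographically smallest read id survives, making
  the filter deterministic and idempotent. A read covers a SNP when the
  position lies in `[start, end)`; reads are treated as ungapped.
* A read on a chromosome absent from the SNP table is `unassigned`, not
  an error; `conflicting` requires matches to both parents at different
  SNPs.
* Fold changes with zero denominators are `+Inf` when the numerator is
  positive and undefined (never a call) when both are zero.
* `interval_methylation()` returns `NA` (undefined) when no covered CpG
  falls in the window; windows clamp at position 0.
* Problem sizes in the test suite and acceptance script — 500-locus
  end-to-end runs, 2,000-gene null simulations, 10,000-case oracle
  grids — were chosen as the smallest sizes at which the Monte-Carlo
  tolerances quoted above are comfortably resolved.

## Known limitations

* The rescue ("became bi-allelic") cutoffs and the bi-allelic DHS class
  are declared conventions, configurable but not sourced.
* The exact NB test reproduces the *structure* of the classic DESeq-style
  test, validated by its own simulation properties (type-I error, power
  monotonicity, oracle agreement), not bit-equivalence with any specific
  package version.
* Nearest-gene assignment uses nearest TSS with a deterministic
  tie-break; bidirectional promoters map to a single gene.
* On real data, mapping bias at SNPs, peak-calling uncertainty and
  replicate-level confounding would all precede this package's inputs;
  peaks, alignments and methylation extractions are consumed as given.
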