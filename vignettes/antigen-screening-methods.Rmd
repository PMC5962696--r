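---
title: "In silico antigen screening: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico antigen screening: models, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taascreen)
```

## The problem

Whole-cell cancer immunotherapies inoculate patients with irradiated,
GM-CSF-secreting allogeneic tumor cells. Whether the treatment can direct an
immune response at the patient's tumor depends on which antigens the cell
line expresses: tumor-associated antigens (TAAs) overexpressed relative to
normal tissue are candidates for breaking immune tolerance, while
immunostimulatory genes (MHC components, costimulatory ligands, cytokines)
determine whether the line can itself act as an antigen-presenting cell.
`taascreen` implements the expression-based computations for this kind of
candidate-antigen audit of a cell line such as SV-BR-1-GM: quality gates and
normalization for the array cohorts, the representative-value conventions,
three screens (Immune Signature, cancer/testis-antigen overexpression, and a
serial three-tier TAA filter with a calibrated verification quotient), an
nCounter-style digital-count normalizer used for orthogonal verification,
and an HLA phenotype-frequency calculator for companion-diagnostic style
questions.

## Quality gates and normalization

Two gates run on **non-normalized** data, both exclusive strictly below
their threshold:

* **RNA integrity**: samples with RIN^e < 7.5 are excluded; a RIN^e of
  exactly 7.5 passes, and samples without a RIN^e pass with the gate marked
  not applicable.
* **Variability**: a sample whose 95th/5th-percentile intensity ratio is
  below 10 is low-variability and excluded; a ratio of exactly 10 is
  retained. A non-positive 5th percentile makes the ratio undefined — the
  sample is flagged and excluded, never a crash.

All percentiles in the package use linear interpolation between order
statistics (`quantile(type = 7)`), recorded on the QC report. Gating happens
before merging cohorts; merged columns are then quantile-normalized
(`limma::normalizeQuantiles`, ties averaged), which forces every column onto
the cross-sample rank-mean distribution. `log2(x + 1)` is applied **only**
before hierarchical clustering (1 − Pearson distance, pairwise average
linkage, the `stats::hclust` implementation and its deterministic
order-based tie handling); every screen threshold operates on linear
quantile-normalized values.

The **background cutoff** is the pooled median over all human RNA-targeting,
non-control probe-sample values of the quantile-normalized matrix. Pooled
versus per-sample is immaterial after quantile normalization — the columns
share one distribution, and a test asserts the two computations agree. A
gene is *expressed* in a sample when at least one of its probes is strictly
above the cutoff. Known-unreliable probes (for example an HLA-DRB3 probe
that reports expression in more samples than allele prevalence permits) are
removed by a blacklist (`drop_probes()`) before any screen.

## Representative values

Screens compare single per-group numbers, computed per probe:

| group | representative |
|---|---|
| each SV-BR-1-GM sample type | arithmetic mean of replicates |
| SV-BR-1-GM (single value) | median of the per-type means |
| non-cultured normal breast types | median |
| cultured normal breast sets | arithmetic mean |
| breast-cancer tissues | pooled 95th percentile |
| normal-tissue panel | 95th percentile of per-group maxima |

The method is a per-group configuration field (`representative_table(...,
methods = )`) so documented exceptions remain expressible. The 95th
percentile is used in place of maxima for the two comparator cohorts to
absorb outliers; no maximum option is offered there. Representatives are
per-probe; gene-level decisions happen downstream through the any-probe
rule, because screening output is reported at probe resolution.

## The three screens

All fold comparisons are strict; the verification quotient is inclusive.
Reported ratios are rounded half-up to 1 decimal (quotients to 2): half-up
is declared for determinism and reproduces every published worked score
cell.

* **Low stringency**: SV-BR-1-GM representative > 1.5× background cutoff
  AND > 1.5× the maximum representative among *all* normal-breast groups
  (cultured + non-cultured).
* **Medium stringency**: additionally > 5× the background cutoff.
* **High stringency (verification)**: surviving genes are mapped by symbol
  to a second (verification) platform; per probe, the quotient of the
  breast-cancer comparator over the normal-tissue comparator is computed and
  a gene is **verified** when any probe's quotient is ≥ 3.00 — a cutoff
  calibrated so that an ERBB2 probe scoring 3.95 is retained. Genes with no
  verification-platform probe are labeled *unverifiable*, not rejected.
* **CTA screen**: SV-BR-1-GM representative > 1.5× cutoff AND > 1.5× the
  maximum representative among *non-cultured* normal breast types AND that
  non-cultured maximum < 1.5× cutoff. The comparator asymmetry with the low
  stringency filter is deliberate: cultured normal cells re-express
  proliferation antigens (the PBK/CEP55 pattern), which must fail the
  cultured+non-cultured comparison yet stand out against non-cultured cells.
* **Immune Signature**: a gene from the queried immunostimulatory list is
  tier 1 when at least one probe exceeds 1.5× the cutoff in *every* retained
  SV-BR-1-GM sample, tier 2 at 5×. "Every sample" means each individual
  retained sample, per the definition's wording; probes vote independently
  and the best probe carries the gene.

`run_taa_pipeline()` applies the serial filters per probe (a probe is
evaluated at medium stringency only if it passed low) and logs attrition at
both probe and gene level, since published gene counts do not state at which
level probes were collapsed.

## Digital-count normalization

`subtract_background()` removes, per lane, the maximum negative-control
count (clipped at zero; a `global` switch uses the maximum across lanes,
since the plural "max. values" admits either reading). `normalize_counts()`
then applies two scaling stages of the same construction — each lane is
multiplied by (arithmetic mean over lanes of per-lane geometric means) /
(this lane's geometric mean) — first on the spiked positive controls, then
on the eight reference genes (*ADRM1, APTX, DGUOK, GNG5, PSMA4, RPL38,
TMEM14C, UBE3C*). This is the standard interpretation of the vendor
normalization, which is named but not specified by formula in the source
protocol. After stage 1 the positive-control geometric means agree across
lanes to machine precision, after stage 2 so do the reference-gene ones.
Zeros are replaced by 1 before geometric means (applied uniformly to control
and reference sets) and the substitution is recorded; a lane whose geometric
mean is non-positive is flagged non-normalizable rather than poisoning the
run. Note the normalization fixes *relative* abundances: rescaling one
lane's raw counts leaves the normalized table unchanged only up to the
single global level set by the cross-lane mean, and the tests assert exactly
that proportionality.

## HLA phenotype frequencies

For a query set of alleles with summed allele frequency ΣAF in a
population, the probability that a diploid individual carries at least one
query allele is

$$\mathrm{PF} = 1 - (1 - \Sigma AF)^2,$$

the squared term encoding Hardy–Weinberg independence of the two
chromosomes — a model assumption, not a configuration knob. Queries run at
allele or allele-group level (group-level PF can only be larger, which is
asserted as a property); query members absent from a table contribute zero
and are reported, and sums above 1 are clamped with a warning because they
signal an inconsistent table. Reports print percentages at 1 decimal.
Per-locus PFs only are computed; cross-locus combinations would require
haplotype frequencies, which are out of scope.

## The synthetic-study generator

`generate_study()` emulates the cohort geometry the screens assume: nine
SV-BR-1-GM sample types, six non-cultured and three cultured normal-breast
groups on the discovery platform, 54 breast-cancer tissues and a 30-group
organ panel on the verification platform, three replicates per group.
Intensities are log-normal — baseline meanlog `log(150)`, sdlog 0.5, which
places the background cutoff near 150, inside the working range of the
published score tables (10²–10³) — with multiplicative planted folds and
mean-one log-normal noise (CV 0.2 by default). Planted genes are pinned at
the baseline median so their fold is a fold-over-background and the expected
verdicts have a closed form; `truth` carries those noiseless verdicts, and
with `noise_cv = 0` the pipeline must (and is tested to) reproduce them
exactly. Planted compartments mirror the real contrasts: `svbr_only`
(passes low+medium, fails verification), `svbr_and_bc` (the verifiable TAA
pattern), and `cultured_normals_too` (the proliferation-antigen pattern that
must fail the cultured+non-cultured arm while passing the non-cultured-only
comparison). Control probes (2%) carry near-zero signal.

For the Immune-Signature cohort the planted folds are 3.5× (tier-1-only)
and 12× (tier-2). These were fixed from a margin argument: under the
every-sample rule with 27 samples and noise CV 0.2, a planted gene must
clear its threshold by more than four noise standard deviations on the log
scale for the planted truth to be unambiguous — 3.5/1.5 and 12/5 both give
≈ 4.2–4.4 σ, while keeping tier-1-only genes comfortably below the tier-2
threshold.

What the generator does **not** emulate: probe-level cross-hybridization,
batch and spatial array artifacts, correlated biological variation between
sample types, heavy-tailed outlier samples, and the mixture structure of
real tissue panels. Passing planted-truth tests therefore demonstrates that
the decision logic is implemented correctly at realistic effect sizes and
noise, not that the screens' published gene counts would reproduce on the
original GEO series — those depend on the deposited cohorts themselves,
which are deliberately not bundled or downloaded.

The allele-frequency generator draws Dirichlet frequencies scaled by a
0.9 listed mass (the remainder models unlisted alleles) and includes the
cell line's typed alleles so default queries resolve. The count-run
generator draws Poisson counts around log-normal gene means with a
log-uniform per-lane scale within the configured spread; the planted scales
are the ground truth for recovery checks (correlation of recovered against
inverse planted factors exceeds 0.99 at 500 genes and 2× spread).

## Numerical choices and degenerate inputs

* Percentiles: type-7 linear interpolation everywhere; boundary tests are
  constructed away from interpolation ambiguity.
* Rounding: half-up with a one-ulp guard, so scores computed as `.x5` minus
  representation error still round up.
* Quantile-normalization ties: tied within-column values receive the mean of
  the rank-mean values for their span (`ties = TRUE`).
* Single-sample matrices pass through quantile normalization unchanged with
  a warning; a constant sample column is an error in clustering (undefined
  correlation) naming the offending sample.
* A gene with no probes is *not evaluable* (`NA`) in expression calls and
  the immune screen — distinct from `FALSE`.
* Merging matrices with colliding sample ids suffixes both sides with their
  dataset labels rather than failing, because independently deposited series
  can share generic column names.
* Matrices never contain missing values; gaps must be resolved upstream.

## Problem sizes used in the checks

The bundled validation exercises deliberately compact instances: planted
recovery uses 2,000 null genes plus 42 planted genes across 10 seeds at 3
replicates per group; quantile-normalization properties use 5,000 × 12;
the Monte-Carlo phenotype-frequency check draws 10⁶ diploid genotypes per
ΣAF; count normalization uses 500 genes × 12 lanes. These sizes give the
property checks sharp expected outcomes (see the test suite and
`scripts/acceptance.R`) while remaining quick to run.

## Known limitations

* The screens are threshold rules, not differential-expression statistics:
  no error control, no variance modeling — faithful to the procedure they
  implement.
* Cross-platform mapping for verification is by gene symbol (with optional
  synonym handling via the caller's annotation); sequence-level probe
  re-annotation is out of scope, so symbol drift between platforms surfaces
  as `unverifiable`.
* The breast-cancer comparator cohort is accession-agnostic; note that the
  source protocol names its comparator series inconsistently in different
  passages, which the loader sidesteps by never keying on accessions.
* Readers handle the TSV/GCT text dialects only; binary scanner formats
  (IDAT/CEL) and raw-signal background correction are out of scope.
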