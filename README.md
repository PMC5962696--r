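# taascreen

Expression-based, in-silico antigen discovery for whole-cell cancer
immunotherapy lines. Given probe-by-sample expression matrices for a
candidate line (e.g. a GM-CSF-secreting breast-cancer line such as
SV-BR-1-GM), normal-breast comparators, breast-cancer tissues and a
normal-tissue panel, the package answers: *which genes does the line
overexpress strongly enough to be candidate tumor-associated antigens
(TAAs), which cancer/testis antigens (CTAs) stand out against non-cultured
normal breast cells, and which immunostimulatory genes does the line express
in every sample?* It is aimed at computational biologists auditing
therapeutic cell lines, and at anyone needing the companion statistics:
nCounter-style digital-count normalization for orthogonal verification, and
HLA "phenotype frequencies" for allele-match prevalence questions.

## The method

* **QC gates** (on non-normalized data): exclude samples with RIN^e < 7.5
  or a 95th/5th-percentile intensity ratio < 10 (both strictly below).
* **Normalization**: quantile normalization across merged cohorts; the
  **background cutoff** is the pooled median over all non-control
  probe-sample values; a gene is *expressed* when any probe is strictly
  above it. `log2(x+1)` and 1 − Pearson average-linkage clustering serve as
  the QC visualization.
* **Representatives**: each SV-BR-1-GM sample type → mean of replicates;
  the line's single value → median of those means; non-cultured normal
  breast types → median; cultured sets → mean; breast cancer → pooled 95th
  percentile; normal tissues → 95th percentile of per-group maxima.
* **Serial TAA filter**: low stringency (> 1.5× cutoff and > 1.5× max
  normal-breast representative), medium stringency (> 5× cutoff), then
  symbol-mapping to a verification platform where the quotient

  `Q = p95(breast cancer) / p95(per-group maxima of normal tissues)`

  verifies a gene when `Q >= 3.00` (calibrated to retain an ERBB2 probe at
  Q = 3.95). Genes without verification probes are `unverifiable`.
* **CTA screen**: > 1.5× cutoff AND > 1.5× the non-cultured (NC)
  normal-breast maximum AND that NC maximum < 1.5× cutoff.
* **Immune Signature**: tier 1 = some probe > 1.5× cutoff in *every*
  SV-BR-1-GM sample; tier 2 = the same at 5×.
* **Phenotype frequency**: for a query allele set with summed frequency
  ΣAF, `PF = 1 − (1 − ΣAF)²` (diploid, Hardy–Weinberg).

A seeded synthetic-study generator plants all of these patterns with ground
truth, and is how the package validates itself end to end. See the methods
vignette (`vignettes/antigen-screening-methods.Rmd`) for conventions,
parameter defaults and limitations.

## Worked example

```r
library(taascreen)

st <- generate_study(study_config(seed = 11, n_null_genes = 300))
res <- run_taa_pipeline(st$svbr, st$normal_breast, st$breast_cancer,
                        st$normal_tissue, st$annotation, st$metadata,
                        st$verification_annotation)
res$cutoff
#> BackgroundCutoff: 153.9 (pooled median over 359 non-control probes x 54 samples)
unlist(res$attrition)
#>                   probes_total                    genes_total
#>                            359                            342
#>                     probes_low                      genes_low
#>                             42                             40
#>                  probes_medium                   genes_medium
#>                             42                             40
#>             genes_unverifiable genes_with_verification_probes
#>                              1                             39
#>                 genes_verified
#>                             20
```

342 genes went in; the 40 genes planted at 8-fold over background survive
low and medium stringency (none of the 300 null genes do), one lacks a
verification-platform probe and is reported `unverifiable`, and the 20
planted in the `svbr_and_bc` compartment — elevated in breast-cancer tissue
as well — pass the verification quotient. The probe-level records show the
CTA asymmetry for the two planted proliferation-pattern genes (high in
cultured normals too, like PBK/CEP55):

```r
subset(res$records, grepl("CTA_CULT", gene_symbol),
       c(gene_symbol, ratio_all, ratio_nc, low_pass, cta_pass))
#>     gene_symbol ratio_all ratio_nc low_pass cta_pass
#> 41 CTA_CULT_001       1.0      6.8    FALSE     TRUE
#> 42 CTA_CULT_002       0.9      6.1    FALSE     TRUE
```

They fail the cultured+non-cultured comparison (ratio ≈ 1) but stand out
6–7-fold against non-cultured cells, exactly the pattern the screen's
comparator asymmetry exists to catch.

```r
phenotype_frequency(0.331)   # probability of carrying >= 1 query allele
#> [1] 0.552439
```

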