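# DemethylSig

Epigenetically silenced genes can be reactivated by DNA-demethylating
drugs such as azacytidine (AZA). DemethylSig is an R package for
scientists analyzing paired methylation/expression experiments of that
kind: it identifies genes whose re-expression after treatment is linked
to promoter CpG-island demethylation, validates them against an
independent tumor cohort, characterizes the resulting signature
(transcription-factor content, gene-set enrichment, promoter motifs),
and stratifies cohort samples by signature expression.

## The method

From methylated (M) and unmethylated (U) bead intensities the package
computes

* beta = M / (U + M) and the M value log2(M / U), masking cells whose
  detection p-value against negative-control background exceeds 0.05;
* Δbeta = beta_treated − beta_mock per probe.

A gene enters the signature when

1. its median expression log2(treated/mock) ratio is > 0.5 at day 3 or
   day 10; and
2. at least one of its CpG-island probes within ±1000 bp of the TSS has
   mock beta > 0.5 and mock − treated Δbeta ≥ 0.25; and
3. in the cohort, one of those probes is *informative* — Spearman
   rho(beta, expression) < 0 at BH-FDR < 0.01 — with rho < −0.25 at
   FDR < 0.05.

Around the cascade the package provides preranked gene-set enrichment
(running-sum ES, gene-set permutation NES, p < 0.05 & FDR < 0.25
selection, NES matrix with 0 for non-significant cells), a PWM best-hit
z-test for promoter motif over-representation in the −450..+50 window,
hierarchical cohort stratification with linked heat-map ordering,
quantile tracks and a random 25-gene control, and the small clinical
formulas (background-subtracted FACS log2 change, RECIST percent change
of summed lesion diameters).

A seeded synthetic-data generator produces the full input suite —
intensity tables, treatment expression arrays, a cohort with a planted
high-methylation/low-expression subgroup, annotation, gene sets, TF
lists, PWMs and promoters — with known ground truth, so every claim the
package makes about itself is measured, not assumed. See
`vignettes/methods.Rmd` for the model, parameter meanings and design
decisions.

## Worked example

```r
library(DemethylSig)
cfg <- simConfig(seed = 101)          # 2000 genes, 50 planted
res <- runPipeline(cfg)
str(res$report$counts)
#> List of 9
#>  $ genes             : num 2000
#>  $ probes            : int 5999
#>  $ masked_fraction   : num 0.00913
#>  $ candidates        : int 50
#>  $ validated         : int 50
#>  $ informative_probes: int 55
#>  $ planted           : int 50
#>  $ recovered         : int 50
#>  $ false_positives   : int 0
res$validated
#> GeneSignature: 50 genes
#>   gene00885, gene00064, gene01021, gene00346, gene01595, gene00040, ...
head(provenance(res$validated), 3)
#>     gene_id  probe_id timepoint beta_mock delta_beta expr_m_max        rho            q
#> 1 gene00021 cg0000060      day3 0.8180086  0.4725729   1.511389 -0.7908864 5.951667e-12
#> 2 gene00040 cg0000113      day3 0.7031882  0.3703760   1.543467 -0.8455289 4.832257e-15
#> 3 gene00055 cg0000158      day3 0.8173980  0.3877896   1.529118 -0.8181717 1.775374e-13
```

About 0.9% of methylation cells fail background detection and are
masked; the cell-line filter passes 50 candidates, all of which survive
cohort validation, recovering all 50 planted genes with no false
positives. Each signature row records the probe, timepoint and values
that carried the gene through the cascade. Downstream,
`res$report$tf_fraction` (0.2) is the transcription-factor share of the
signature, `res$report$motif` holds the promoter motif z-test
(z ≈ 10.4, p ≈ 1e-25 for the planted motif), and
`res$report$stratification` shows the cohort clustering agreement
(adjusted Rand index 1 against the planted subgroup, ≈ 0.04 for random
25-gene controls).

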