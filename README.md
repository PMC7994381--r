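# nbscreen

Multi-criteria driver-gene screens for neuroblastoma genomics.

Segmental gain of distal chromosome 17q is the most frequent copy-number
lesion in neuroblastoma, and *MYCN* amplification its best-known marker of
aggressive disease.  A recurrent analytical problem in this setting is
prioritisation: a gained region carries hundreds of transcripts, almost
all of which show a copy-number dosage effect, so no single statistic
separates a driver from its passengers.  `nbscreen` implements two
screens that address this by intersecting orthogonal evidence, together
with a synthetic-cohort generator so the whole pipeline can be exercised
and calibrated without any external data.

**The cohort screen** scores every gene of a recurrently gained region
against five criteria:

1. up-regulation in region-gain vs diploid tumours (negative-binomial
   Wald test; Benjamini–Hochberg adjusted p < 0.05 and log2 fold-change at
   or above the lower quartile of all positive significant log2
   fold-changes — a data-dependent threshold),
2. up-regulation in *MYCN*-amplified vs non-amplified tumours (same rule,
   its own threshold),
3. positive Pearson correlation of expression with the gene's own copy
   number (Bonferroni-adjusted p < 0.05, r > 0),
4. positive Pearson correlation with *MYCN* expression (same rule),
5. association with poor outcome: hazard ratio > 1 and log-rank p < 0.05
   for the cohort dichotomised at median expression.

A gene's score is the number of criteria passed (0–5); candidates are the
score-5 genes.  Copy-number input is per-sample segment tables with an
average ploidy *n* per segment, summarised in 10-kb bins and classified
loss (*n* ≤ 1), diploid, or gain (*n* ≥ 3).

**The ChIP screen** nominates coactivator targets from called peak sets:
a gene passes with (1) promoter co-occupancy (window −1000/+100 bp around
the TSS) of MYCN, RNA Pol II, H3K27ac and H3K4me3 together with ALYREF
binding, (2) ALYREF fold enrichment FE > 5 (strict), (3) the survival
filter, (4) the *MYCN*-correlation filter, and (5) membership in a
user-supplied gene set; final targets are ordered by FE rank.  An E-box
scanner annotates canonical (CACGTG) and non-canonical (CANNTG) motifs.

## Worked example

```r
library(nbscreen)

cfg    <- sim_config(seed = 7)      # default study conditions
cohort <- simulate_cohort(cfg)
cohort
#> Synthetic cohort: 200 samples, 401 genes (60 in chr17:5000000-8000000), driver G370
#>   region gain: 104 samples; MYCN-amplified: 56 samples

screen <- five_criteria_screen(cohort)
print(screen, n = 5)
#> Five-criterion screen over 60 genes in chr17:5000000-8000000
#>   strata: 104 gain / 96 diploid; 56 amplified
#>   log2FC thresholds: gain 0.643, amplified 0.313
#>   genes passing all five criteria: G370
#>  rank gene_id score c1_de_gain c2_de_amp c3_cn_corr c4_mycn_corr c5_survival
#>     1    G370     5       TRUE      TRUE       TRUE         TRUE        TRUE
#>     2    G368     4       TRUE      TRUE       TRUE        FALSE        TRUE
#>     3    G364     3       TRUE     FALSE       TRUE        FALSE        TRUE
#>     4    G380     3       TRUE     FALSE       TRUE        FALSE        TRUE
#>     5    G377     3       TRUE     FALSE       TRUE        FALSE        TRUE

summary(screen)
#> Screen over 60 genes
#> Per-criterion pass counts:
#>   c1_de_gain    c2_de_amp   c3_cn_corr c4_mycn_corr  c5_survival
#>           45            4           60            1           14
#> Score distribution:
#>  0  1  2  3  4  5
#>  0 12 35 11  1  1
#> Score-5 genes: G370
```

The reading: 45 of the 60 region genes are up-regulated with the gain and
all 60 track their own copy number — the dosage effect, shared by
passengers.  Only the planted driver G370 also rises with amplification,
correlates with *MYCN* and predicts poor survival, so it is the single
score-5 candidate.  The ChIP screen works the same way:

```r
fx  <- simulate_chip_fixture(cfg)
res <- chip_target_screen(fx$peaks, fx$cohort$counts, fx$cohort$clinical,
                          fx$gene_set, genes = fx$genes)
res$gene_id[res$final_pass]       # the planted target, at FE rank 1
```

A command-line interface covering `simulate`, `screen`, `chip-targets`
and the individual stages is installed under
`system.file("cli", "nbscreen.R", package = "nbscreen")`; outputs are
byte-identical across repeated runs at a fixed seed.

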