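# azadem

Genome-wide analysis of DNA demethylation by 5-aza-2'-deoxycytidine
(decitabine) and its regulatory consequences, as a tested, reusable R
pipeline.

5-aza-CdR is incorporated into replicating DNA and traps DNMT1, causing
passive genome-wide loss of 5-methylcytosine. For a treated-versus-control
design (two doses, an acute 3-day time point and a 30-day drug-free
recovery), `azadem` quantifies what that demethylation did and where it
landed:

* **Global methylation** from LUMA (luminometric methylation assay)
  pyrosequencing runs:
  `%5mC = 100 × (1 − (HpaII_CG / HpaII_norm) / (MspI_CG / MspI_norm))`,
  each CCGG digestion normalized by its own EcoRI (A+C)/2 signal.
* **Per-site methylation** from HpaII/MspI (HELP-tagging) count data:
  the angle score `100 × (2/π) × arctan(h/m)` on normalized counts, in
  [0, 100] with higher = less methylated.
* **Compartmentalization** of the genome with a batch self-organizing map
  over 100-kb sliding-window features (control/treated methylation, mean
  expression, CCGG density), with U-matrix visualization and a Fisher
  exact test for enrichment of top-demethylation windows in the
  euchromatic (top-expression, top-methylation) partition.
* **Promoter classes** by CG dinucleotide observed/expected ratio
  (`obs × L / (nC × nG)` over TSS ± 1.5 kb) split into HCG/LCG at the
  valley of the bimodal ratio distribution, plus the methylated-LCG subset
  below the HCG reference band (`mean − 1.96 × sd`).
* **Methylation/expression trajectories** across acute and recovery,
  clustered with k-means (k-means++ seeding, k = 7) into no-change plus
  loss/gain × early/late/transient, with induction fractions reported
  against all loci tested from the outset.
* **Peak dynamics**: concordant/new/lost RNA-polymerase peaks between
  conditions, genic context (promoter = TSS ± 2 kb > intragenic >
  intergenic), the methylation shift at new intragenic peaks, and
  activation of previously silent genes.
* **Intron retention**: `IRS = 2I/(E + I)` from exon/intron coverage
  densities, with symmetric log-ratio flagging at 2 SD and an exact
  binomial symmetry verdict.

A synthetic-data generator (`sim_config()`, `generate_bundle()`) builds a
small two-compartment genome with all of these effects planted —
dose-dependent demethylation targeted to euchromatin, a partial
methylation "imprint" after recovery, sparse expression changes,
treatment-only intragenic peaks in silent genes — so the whole pipeline
runs end to end with no downloads.

## Worked example

Single operations are plain functions with closed-form behavior:

```r
library(azadem)

luma_methylation(32, 50, 100, 50)
#> [1] 68

angle_score(c(0, 5, 12), c(10, 5, 4), 100, 100)
#> [1]  0.00000 50.00000 79.51672

irs(c(100, 300), c(1000, 1500), 500, 500)
#> [1] 0.125
```

The 68 is percent methylation: the HpaII reaction incorporated 0.64
normalized units against 2.0 for MspI, so 32% of CCGG sites cut, 68%
methylated. The angle scores read 0 (fully methylated site), 50 (equal
HpaII/MspI signal), ~80 (mostly unmethylated). The IRS of 0.125 says
intronic read density is a small fraction of exonic (E = 15, I = 1,
2×1/16).

The full pipeline simulates its reference conditions and runs every stage:

```r
res <- run_all(run_config(outdir = "azadem_run", seed = 7))
str(res$summary$scores$global_methylation)
#> List of 5
#>  $ control      : num 67.1
#>  $ acute_0.25   : num 51.5
#>  $ recovery_0.25: num 55.8
#>  $ acute_1.0    : num 38.8
#>  $ recovery_1.0 : num 50.4
```

Control cells sit near 68% global methylation; exposure depletes that in a
dose-dependent way (51.5% at 0.25 uM, 38.8% at 1.0 uM), and after 30 days
of recovery methylation returns only part of the way (50.4% for the 1.0 uM
cells) — the pharmacological imprint.

```r
str(res$summary$som$enrichment_response_expression)
#> List of 2
#>  $ odds_ratio: num 4.59
#>  $ p_value   : num 2.99e-06
```

Windows in the top demethylation-response quintile are strongly enriched
among top-expression windows: the drug targets euchromatin.

```r
str(res$summary$cluster)
#> List of 6
#>  $ n_units      : int 90
#>  $ loss_pct     : num 54.4
#>  $ gain_pct     : num 31.1
#>  $ no_change_pct: num 14.4
#>  $ induced_pct  : num 1.11
#>  $ n_induced    : int 1
```

Over half of the LCG promoter units lose methylation, yet ~1% of units
show expression induction — demethylation is uncoupled from transcription.

```r
str(res$summary$irs[c("n_increased", "n_decreased", "shift_p", "verdict")])
#> List of 4
#>  $ n_increased: int 9
#>  $ n_decreased: int 15
#>  $ shift_p    : num 0.307
#>  $ verdict    : chr "no systematic shift"
```

Intron retention flags are symmetric between directions: no systematic
shift in primary-transcript processing.

Reruns resume: each stage keeps an input-content manifest and is skipped
when nothing changed. A thin CLI wrapper ships in `inst/scripts/azadem`
(`azadem simulate --seed 7 --out dir`, `azadem run-all --seed 7 --out dir`).

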