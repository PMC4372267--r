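---
title: "azadem: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{azadem: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

5-aza-2'-deoxycytidine (5-aza-CdR, decitabine) is a cytidine analog that is
incorporated into replicating DNA, where it irreversibly traps DNMT1 and
causes passive, genome-wide loss of 5-methylcytosine. `azadem` implements a
pipeline for characterizing that demethylation and its regulatory
consequences in a treated-versus-control design with two doses (0.25 and
1.0 uM), an acute time point (3 days of exposure) and a recovery time point
(30 days of drug-free culture):

1. **global methylation** from LUMA pyrosequencing runs, and **per-CCGG-site
   methylation** from HpaII/MspI (HELP-tagging) count data;
2. **genome compartmentalization** with a self-organizing map over 100-kb
   window features, and an enrichment test of where demethylation lands;
3. **promoter classification** by CG observed/expected ratio into HCG/LCG
   at a data-driven bimodal cutoff, and isolation of the methylated-LCG
   promoter subset;
4. **trajectory clustering** (k-means, k = 7) of promoter methylation
   across acute and recovery stages, with linked expression induction;
5. **peak dynamics**: treatment-only RNA-polymerase peaks, their genic
   context, methylation shift, and activation of silent genes;
6. **intron retention scoring** from exon/intron coverage.

A synthetic-data generator produces a small genome with all of these
effects planted, so the full pipeline is testable end to end without
external data.

All internal coordinates are 0-based half-open; 1-based closed conventions
(GTF, GRanges) exist only at I/O boundaries.

# Methylation scores

**LUMA.** Percent methylation is
`100 * (1 - (hpaii_cg/hpaii_norm) / (mspi_cg/mspi_norm))`: HpaII cuts only
unmethylated CCGG, MspI cuts regardless, and each reaction is normalized by
its own EcoRI (A+C)/2 signal. The conventional (A+C)/2 normalizer is an argument of
`luma_methylation()`, so a different normalization convention costs
nothing. Replicate digestions are scored
individually and averaged afterwards, matching per-reaction normalization.
Output is clamped to [0, 100] because replicate noise can push the ratio
slightly past either endpoint.

**Angle score.** Per site, with library-size-normalized counts
`h = hpaii/hpaii_libsize` and `m = mspi/mspi_libsize`, the score is
`100 * (2/pi) * atan(h/m)`: 0 for a fully methylated site, 50 when the
normalized signals are equal, approaching 100 for a fully unmethylated
site. The transform is monotone increasing in HpaII and decreasing in MspI
signal and satisfies the complementarity `s(h, m) + s(m, h) = 100`. Historical implementations of the angle computation differ in their exact
normalization, so this form is pinned here by the required 0-100 range
and the sign convention (higher = less methylated).

**Library sizes.** `methylation_track()` treats the two channels as
depth-matched by default (the raw count ratio carries the signal). This is
deliberate: normalizing each channel by its own realized total re-centers
every condition's mean near 50 under global demethylation — the
between-condition signal (dose response, the recovery imprint) would be
normalized away. Absolute global levels are the job of LUMA; the tracks
must stay comparable across conditions. For libraries of genuinely unequal
depth, pass explicit `hpaii_libsize`/`mspi_libsize`.

Sites with `mspi < min_mspi` (default 1) have no usable reference and are
removed from the track — absent, not scored zero.

# SOM compartmentalization

Windows are 100 kb on a 50-kb lattice, only fully contained windows kept.
Features per window: mean control angle score, mean treated (1.0 uM acute)
angle score, mean control FPKM of genes whose TSS lies in the window, and
the cumulative CCGG count. Windows missing a feature (no site or no gene)
are excluded and counted. Features are z-scored before training because
their ranges differ by orders of magnitude.

Quantile tags are quintiles (equal-frequency bins 1-5). Tags: methylation (on the level scale `100 - angle`, 5 = most
methylated), expression (5 = most expressed), and demethylation response
(`treated - control` angle, 5 = most demethylated). The response tag is an
overlay label only, never a training feature ("tagged by", not trained on).

**Training** is classic Kohonen batch learning: each epoch assigns every
vector to its best-matching unit (minimum Euclidean distance), then
replaces each node weight with the Gaussian-neighborhood-weighted mean of
the data. The radius decays linearly from half the larger grid dimension
to 0.5. One non-classical ingredient: an epoch's batch update is accepted
only if it does not increase the quantization error; a rejected epoch just
advances the radius schedule (a trust-region-style acceptance). Plain
batch updates under a decaying radius are not strictly monotone in QE, and
we want the monotonicity contract to hold exactly, not just usually.
Defaults: 20 x 20 grid, 100 epochs in `train_som()`; the bundled pipeline
uses 6 x 6 and 50 epochs because the synthetic genome yields ~300 windows
(a 400-node grid would be badly under-determined, and `train_som()` warns
below 5 vectors per node).

The U-matrix is the per-node mean Euclidean distance to its 4-connected
lattice neighbors; a high-valued ridge separates compartments.

**Enrichment overlay.** Windows are cross-tabulated by membership in the
top quintile of two labels and tested with a two-sided Fisher exact test;
the sample odds ratio is reported (infinite and degenerate tables reported
as such, never silently patched). On the default fixture the
response-by-methylation association is extremely strong, while the
response-by-expression association is positive but noisier: windows rich
in active promoters are already hypomethylated there and hence partially
refractory to further loss — the same refractoriness the drug literature
describes. The pipeline reports both pairings.

# Promoter CG classification

`cg_obs_exp()` uses the standard observed/expected definition
`(#CG * L) / (#C * #G)` with an overlapping dinucleotide scan; N bases are
excluded from the mononucleotide counts and from `L`, and a sequence with
no C or no G scores 0 by convention. Promoter regions are TSS +/- 1.5 kb
(a 3-kb window), the same flank for annotation-defined and peak-defined
promoters (configurable).

The HCG/LCG cutoff is the lowest interior local minimum between the two
highest modes of a Gaussian KDE (Silverman bandwidth, 512-point lattice on
[0, max]); density maxima below 1% of the peak height are ignored as
numerical tail noise. A unimodal density is a classed error carrying the
mode location so the caller can impose a manual cutoff. Ties at the cutoff
classify as HCG, so classification is deterministic.

The "methylated LCG" subset uses the HCG promoters as a normal reference
band for unmethylated scores and takes LCG promoters below
`mean(HCG) - 1.96 * sd(HCG)`. This is a reference band, deliberately not a confidence interval of the
mean: a CI of the mean
shrinks as n grows and would eventually select nearly every LCG promoter,
which contradicts the visual bimodality the subset is meant to capture.

# Trajectory clustering

Trajectories are two-dimensional: (acute - control, recovery - control).
Methylation trajectories are computed on the **level** scale
(`100 - angle`), so a negative delta means demethylation; expression
trajectories are log2 fold changes (pseudocount 0.1), so a positive delta
means induction. With these conventions one set of semantic labels fits
both data types: the centroid with smallest norm is *no-change*, and the
remaining six are matched one-to-one to the directional prototypes
loss/gain x early (persistent change), late (recovery-only), transient
(acute-only) by minimizing total cosine distance over all assignments.

k-means is Lloyd's algorithm with k-means++ seeding, best of 25 restarts
by within-cluster sum of squares; an emptied cluster is re-seeded at the
point farthest from its assigned centroid (which cannot increase the
WCSS). k = 7 is part of the analysis design, not selected by any
model-selection rule.

Cluster proportions are always percentages of the units tested from the
outset, so the induced-expression percentage is directly comparable to the
methylation-cluster percentages. The induction call itself is deliberately
simple plumbing (transcript-assembly differential testing is out of
scope): per gene, Welch t-test on `log2(FPKM + 0.1)` across the 4
pseudo-replicates, BH correction, and a call at `|log2FC| >= 1`,
`q < 0.05`; all thresholds are arguments.

# Peak dynamics

A treated peak is concordant if it overlaps any control peak by at least
`min_overlap` bp (default 1); otherwise new. Control peaks matched by
nothing are lost. Genic context uses promoter = TSS +/- 2 kb, intragenic =
gene body minus promoter, intergenic otherwise, judged at the peak summit
when present (whole-peak overlap otherwise) with priority
promoter > intragenic > intergenic, so classes are exhaustive and mutually
exclusive; a peak that is promoter to one gene and intragenic to another
is a promoter peak.

The methylation shift at new peaks is the per-peak mean angle delta
(treated - control) over contained sites, tested one-sided (delta > 0 =
demethylation) with a Wilcoxon signed-rank test; peaks without sites are
excluded and counted, and a single usable peak skips the test with a
warning rather than fabricating a p-value.

"Completely silent" is FPKM below 0.5 in **all** replicates (0.5 is a
common practical floor and is configurable). Activation = silent before and not silent after.

# Intron retention

With `E = sum(exon coverage / exon length)` and `I` the intronic
equivalent, `IRS = 2I / (E + I)`, algebraically bounded in [0, 2] and
scale-invariant in coverage. Genes without introns, or with no coverage at
all, are excluded with a reason, and excluded + scored = input. Coverage
is aggregated from a bedGraph depth track over the collapsed (isoform-
union) exon structure, so shared exons are never double-counted.

Condition ratios use epsilon-regularized scores
(`(irs_t + 0.01) / (irs_c + 0.01)`) and flags are set on log-ratio
z-scores at 2 SD; the log scale makes gains and losses symmetric, and the
epsilon handles zero-control genes without dropping them. Flagging on the raw-ratio
scale would treat gains and losses asymmetrically; the log-scale reading
is pinned and configurable. The symmetry verdict is an
exact binomial test of increased vs decreased counts against 0.5.

# The synthetic genome

`sim_config()` defaults define the reference conditions used throughout
the tests:

* **Genome**: 2 chromosomes x 7.5 Mb, compartment segments of 500 kb with
  40% euchromatin (exact allocation, shuffled).
* **Methylation** is parameterized on the level scale. Baselines 80
  (euchromatin) vs 60 (heterochromatin): euchromatin is simultaneously the
  more expressed and the more methylated compartment — the paradoxical
  co-enrichment the compartment analysis is designed to recover. CCGG
  spacing is 200 bp in euchromatin vs 800 bp in heterochromatin, so
  ~64% of sites are euchromatic and the site-weighted control global lands
  near 68%, a typical untreated global methylation level for cultured
  human cells.
* **Demethylation** removes 25 (0.25 uM) or 40 (1.0 uM) level points in
  euchromatin, a quarter of that in heterochromatin, scaled per site by
  `base / baseline`: a locus only loses what it carries, so
  already-hypomethylated promoters are refractory. Recovery retains 60% of
  the acute shift (the pharmacological imprint), hence the recovery mean
  always sits strictly between acute and control.
* **Genes**: 300 per chromosome, 75% coding / 25% lncRNA, 1-6 exons
  (exons 200-500 bp, introns 400-1200 bp). Active-gene FPKM is log-normal
  (median 30 in euchromatin, 2 in heterochromatin); 20% / 30% of
  eu/het genes are silent (FPKM ~ U(0.01, 0.1)). 1% of coding and 3% of
  lncRNA genes carry a planted 4-fold change (71% up), 20% of which is
  retained at recovery; 4 pseudo-replicates per condition with log-normal
  noise (sdlog 0.2).
* **Promoters**: CG obs/exp component per gene from a 0.2/0.6 mixture
  (SD 0.05), silent annotations LCG-enriched (P(LCG) 0.8 vs 0.25).
  Promoter sequence is synthesized to the target ratio and the CCGG site
  list is taken from a scan of the final FASTA after planting (incidental
  CCGG occurrences are mutated away), so sequence and site table are
  consistent by construction. Active promoters are hypomethylated
  (level 12) except a planted 35% of active LCG promoters that stay
  methylated while expressed — the polymerase-on-methylated-DNA subset.
* **Peaks**: control peaks at every active promoter; the treated set adds
  15 treatment-only peaks in the bodies (outside TSS +/- 2 kb) of silent
  euchromatic genes (~2.5% of genes, a realistic scale for
  treatment-induced intragenic promoter gains). 70% of those genes are
  activated (FPKM 8) after treatment.
* **Coverage** for intron retention is negative binomial per feature
  (per-base depth 2, size 10, intron mean = 5% of exonic), identical in
  distribution between conditions: the reference conditions are a
  symmetric null, matching the finding of no systematic retention shift.

`generate_bundle()` writes FASTA, GTF, site-count/expression/LUMA tables,
peak BEDs, coverage bedGraphs, ground truth and the YAML config; each
internal stage draws from a seed derived from the master seed
(`derive_seed()`), so bundles are byte-reproducible and components can be
regenerated independently.

**What the generator does not emulate:** read-level sequencing (no FASTQ,
no alignment or mapping artifacts), isoform structure (one collapsed model
per gene), chromatin features beyond the two-compartment caricature, CpG
islands as spatial entities (only the promoter ratio), allele-level
methylation mixtures, and replicate structure beyond i.i.d. log-normal
noise. Passing tests therefore demonstrate the pipeline's arithmetic,
contracts, and power against planted effects of realistic size — not
performance on real sequencing data.

# Numerical and reproducibility choices

* One global seed fans out per stage via `derive_seed(seed, stage)` (a
  polynomial string hash mod 2^31), so any stage can be rerun in
  isolation with the same stream.
* `run_all()` writes a manifest (MD5 of inputs + parameter digest) per
  stage and skips stages whose inputs are content-identical; deleting a
  stage's summary fragment forces just that stage to recompute.
* Replicate-based null checks in the test suite run at reduced problem
  sizes chosen for statistical sufficiency: the zero-effect enrichment
  null uses 40 replicates of a 1 x 2 Mb genome (the null property is
  size-free), and the retention-symmetry null uses 40 replicates of 400
  simulated genes. The planted-retention recovery check runs at the
  stated n = 5000.
* Ties: classification at the CG cutoff goes to HCG; k-means BMU and
  assignment ties go to the first index; duplicate centroids in labeling
  are broken by cluster index with a warning.
* Degenerate inputs have pinned behaviors rather than crashes: empty LCG
  subsets are empty results, single-peak shift tests are skipped with a
  warning, zero flagged genes yield a "no flags" verdict, degenerate
  Fisher margins report `NA` odds ratios.

# Known limitations

* The angle score is a relative measure; with depth-matched normalization
  absolute site scores are comparable across conditions, but they are not
  calibrated percent-methylation values. LUMA anchors the absolute scale.
* The response-by-expression window enrichment is intrinsically noisier
  than response-by-methylation (promoter-rich windows are partially
  refractory); on some generator seeds its Fisher p sits near 0.05 even
  though the compartment targeting itself is unambiguous.
* The induction caller is a t-test stand-in, not a transcript-level
  differential pipeline; its calls are used for linkage bookkeeping, not
  as a methods contribution.
* With k fixed at 7, clusters partition noise when fewer than seven real
  trajectory groups exist; small "gain" clusters on a pure-loss fixture
  are an expected artifact of the forced one-label-per-cluster scheme.
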