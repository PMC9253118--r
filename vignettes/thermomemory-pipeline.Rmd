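---
title: "Methods: the thermomemory transcriptomic inference chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the thermomemory transcriptomic inference chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermomem)
```

# Scope

`thermomem` re-implements, as a tested pipeline, the inference chain used to
study heat-stress memory (thermomemory) in *Arabidopsis*: a qRT-PCR screen of
a NAC transcription-factor panel, RNA-seq differential expression with
heat-by-genotype interaction contrasts, promoter-proximal binding evidence
from DAP-seq-style peaks, candidate direct-target filtering, weighted
co-expression networks with hypergeometric target enrichment, and the
chlorophyll / fresh-mass phenotype quantifications. A synthetic-data
generator with recorded planted truth makes every stage verifiable without
external downloads; the `analysis/` scripts in the source repository run the
chain end to end on one generated data set.

# The comparative-Ct screen

Expression is quantified by the comparative-Ct rule. For each gene and
sample, technical replicates are averaged arithmetically and the cycle
threshold is normalized against the reference gene measured in the same
sample, `dCt = Ct_gene − Ct_ref`. Expression is reported as `40 − dCt`, a
monotone score on the log2 scale (higher = more expressed): on that scale a
log2 fold change between two treatment arms is a plain difference of arm
means at the matched clock time, which is the delta-delta-Ct identity. The
pipeline asserts this identity as a property: adding a constant to every Ct
value of a sample (including the reference) leaves all fold changes
unchanged.

Decisions the assay description leaves open, and how they are fixed here:

* **Detection ceiling.** A gene is undetectable in an arm if no sample of
  that arm has raw Ct below the ceiling (default 38 cycles), and
  undetectable overall if that holds in every arm. Undetectable genes carry
  no ratios and are excluded from clustering and DE calling.
* **DE boundary.** A gene is differentially expressed when
  `|log2 ratio| ≥ log2(1.5)` at *any* timepoint, boundary inclusive;
  direction is the sign at the maximal-|ratio| timepoint. Both the
  threshold and the any-timepoint rule are configurable.
* **Clustering.** k-means on the per-gene log2-ratio trajectories,
  Euclidean distance, best of 25 random restarts under a fixed seed
  (`stats::kmeans`); labels are renumbered by decreasing cluster size so
  partitions are stable across runs. Genes missing single timepoints are
  imputed with their own row mean for clustering only — never for DE
  calling, so no DE call is ever made on an imputed value.

# Differential expression

Counts enter the linear-model framework through a precision-weighted log-CPM
transformation: `log2((count + 0.5) / (libsize + 1) × 1e6)`. A shared-design
ordinary least-squares pass provides fitted values and residual standard
deviations; the gene-wise mean log-count versus sqrt-residual-sd trend is
smoothed by locally weighted regression (span 0.5, 2 robustness iterations)
and evaluated at each observation's fitted value; the observation weight is
the predicted standard deviation to the power −4 (an inverse-variance
weight, since the trend is fitted on the square-root-sd scale). The
expression matrix is then quantile-normalized onto the column-mean reference
distribution; weights are fitted *before* normalization and kept fixed.
Quantile normalization assigns strictly by rank (ties broken by order), so
after normalization every column carries exactly the reference multiset — an
invariant the tests assert. With fewer than ten genes the mean-variance
trend is not estimable and unit weights are used.

Each gene is fitted by weighted least squares on the saturated cell-means
design `~ 0 + genotype.condition.timepoint` — a single joint model over all
cells rather than per-timepoint subsetting, so residual degrees of freedom
are pooled as the contrast framework implies. Residual variances are
moderated by empirical Bayes: the scaled-F prior `(d0, s0²)` is estimated by
moment matching of `log s_g²` (the prior degrees of freedom via a Newton
inversion of the trigamma function), and the posterior variance is
`(d0·s0² + d_g·s_g²) / (d0 + d_g)`. When the observed variances show no
excess spread beyond chi-squared sampling noise the prior is degenerate:
`d0 = ∞` and every posterior variance equals the mean observed variance. At
the other limit, `d0 = 0` reduces the moderated t to the ordinary t — both
limits are tested, and the estimator is cross-checked against an independent
reference implementation on simulated scaled-F draws.

The scientific contrast of interest is second-order:
`(heat − control)_genotype − (heat − control)_WT` per timepoint, which
cancels constitutive genotype differences and generic heat responses and
isolates the genotype-dependent heat response. Significance is decided
globally: p-values of *all* genes and *all* contrasts are pooled into one
Benjamini-Hochberg step-up adjustment (FDR 0.05, |log2FC| ≥ 0 by default,
both configurable). Sample-level diagnostics are the Pearson correlation
matrix over genes (average-linkage ordering on 1 − r for display) and
classical (Torgerson) multidimensional scaling of the Euclidean
between-sample distances, which reproduces the distances exactly whenever
the configuration truly has the embedding dimension.

# Promoter binding and candidate targets

Gene models are read from GFF3 (1-based inclusive), peaks from narrowPeak
(0-based half-open, converted to 1-based inclusive internally; all outputs
state their convention). The TSS is `start` on the plus strand and `end` on
the minus strand. The nearest-TSS distance of a peak is 0 when the TSS lies
inside the peak and the edge gap otherwise; equidistant genes are all
reported with a tie flag, and the lexicographically lowest gene id is the
deterministic winner. A gene is *promoter-bound* when at least one peak
overlaps its strand-aware open upstream window `(TSS − 1000, TSS)` (mirrored
for minus-strand genes). Whether the whole peak or only its summit must fall
in the window is not decidable from the assay description; any-overlap is
the default and a summit mode is provided (summit −1 resolves to the
interval midpoint). Both the distance computation and the window rule are
verified against brute-force all-pairs / position-set oracles on random
instances.

Candidate direct targets combine three filters, in this order: (1)
*discordance* — the OE-versus-WT interaction decision is +1 while the
KO-versus-WT decision is −1 at the same timepoint (or mirrored); both
significant calls are required, a conjunction, because the published
analysis intersects the two lists; (2) *binding* — the gene is
promoter-bound; (3) *commonality* — the same gene and direction are
supported at ≥ 2 of the 3 timepoints (the all-timepoint subset is also
reported). Priming-associated "sustained" sets ship in two stringencies,
since the cited criteria are not restated in full: `strict` requires a
significant same-sign call at every timepoint; `lenient` requires
significance at the first timepoint and a same-sign logFC later. Neither is
asserted to be the original; `strict` is the default.

# Co-expression network

The unsigned weighted network raises `|cor|` to the soft-thresholding power
β (default 6; a signed variant `((1 + r)/2)^β` is available). The power scan
reports, per candidate β, the mean connectivity and the scale-free fit
index: connectivities are binned into 10 equal-width bins, empty bins
dropped, and `log10(frequency)` regressed on `log10(mean bin connectivity)`;
the index is `−sign(slope) · R²`, so a topology with *more* frequent
high-degree nodes is penalized. Equal-width binning is deliberate:
equal-count bins have constant frequency by construction and make the
regression degenerate.

Topological overlap is
`TOM_ij = (Σ_{u≠i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)` with
`TOM_ii = 1`. Modules are detected by average-linkage clustering of
`1 − TOM` with a *static* cut (height 0.99) and minimum size 30; clusters
below the minimum are relabelled 0 (unassigned) and surviving modules are
renumbered by decreasing size. The static cut is an explicit approximation:
dynamic tree cutting is a reasonable alternative, but the static rule is
fully reproducible from two parameters and both are exposed. Module
eigengenes are first principal components of the standardized module
expression, sign-anchored to a positive mean gene loading.

Enrichment of transcription-factor target sets per module uses the
upper-tail hypergeometric probability with the *network genes* as the
universe (overrepresentation is asked relative to clustered genes, not the
genome); when several sets are supplied their pairwise intersections are
tested too, and all module × set tests are BH-adjusted jointly. The
hypergeometric tail is verified against exhaustive enumeration for every
configuration with a universe of at most 12 genes, to 1e-12.

# Phenotype quantification

Chlorophyll concentrations apply the published coefficient set verbatim
(after multiplying absorbances by the dilution factor):
`Chl_a = 0.0127·OD663 − 0.00269·OD645`,
`Chl_b = 0.229·OD645 − 0.00488·OD663`,
`Total (g/L) = 0.202·Chl_a + 0.00802·Chl_b`,
`Total (mg/g FM) = (20.2·Chl_a + 8.02·Chl_b)/FM`. This coefficient set is
internally inconsistent with the classical Arnon coefficients (the `Chl_b`
factor is 10× the classical value, and the total mixes two scales); it is
nevertheless implemented exactly as printed, negative results are kept but
flagged, and `classic_arnon = TRUE` switches to the standard coefficients as
a clearly separate convention. No intent is guessed. Fresh-mass ratios are
stressed-mean over control-mean per genotype (dispersion across replicate
ratios; Welch t reported descriptively), and recovery classes are an input
labelling converted to proportions.

# The synthetic-data generator

The generator is first-class, tested code, and its defaults define the
study conditions every recovery test runs under:

* **Design**: 3 genotypes (WT, overexpressor, knockout) × 2 conditions
  (control, heat priming) × 3 memory-phase timepoints (0 h, 1 h, 4 h) × 3
  biological replicates — 54 RNA-seq samples. These are the factors the
  study design states; we note the four factor cardinalities do not
  reproduce every sample count quoted for the original experiment, and the
  generator follows the factors.
* **Counts**: negative-binomial, dispersion 0.05, log-normal library sizes
  around 2×10⁶ reads, log-normal baseline composition over 2000 genes.
  Generic heat effects (30% of genes, log2 effect sd 1) decay over the
  memory phase; constitutive genotype effects (10% of genes, sd 0.3) cancel
  in the interaction contrast by construction.
* **Planted targets**: 50 genes, half activated / half repressed, each with
  a heat-by-genotype interaction of magnitude 2 (log2) — positive in the
  overexpressor and negative in the knockout for activated targets,
  mirrored for repressed — at all three timepoints with probability 0.4,
  otherwise at a random two, so the 2-of-3 commonality rule has positives.
  The effect magnitude is a free parameter because the original magnitudes
  are not published; 2 log2 units is a strong but realistic
  transcription-factor effect.
* **Genome and peaks**: one synthetic chromosome, non-overlapping 2-kb gene
  models on both strands with 8-kb intergenic spacing; every target (and a
  set of bound-but-unregulated genes) receives one peak wholly inside its
  strand-aware 1-kb upstream window; decoy peaks are placed > window + 1 bp
  from every TSS, so by construction they can never qualify.
* **Modules**: a per-module Gaussian latent factor added on the log2 scale,
  scaled against the NB log-noise to hit a target within-module correlation
  (`module_cor`).
* **qPCR panel**: 104 genes including a flat reference; 29 planted
  undetectable (Ct above the ceiling everywhere); the rest follow
  cluster-centre log2 trajectories from a small shape library plus per-gene
  jitter, with Ct noise sd 0.25 cycles.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: sequence content and read-level artefacts
(alignment and counting are out of scope; the pipeline consumes count
matrices), realistic chromosome structure and overlapping gene models,
batch effects, outlier samples, correlated library composition shifts, and
amplification-efficiency differences between qPCR primer pairs.

Every generator call is deterministic for a fixed seed (file output is
byte-identical), and the separate stages draw from seed offsets so that,
e.g., the Ct table does not perturb the count draws.

# Numerical choices and degenerate inputs

* Moderated-t p-values are two-sided; BH pooling order is fixed, so results
  are reproducible to the bit for a given input.
* `lowess` trend: span 0.5, 2 robustness iterations; predicted standard
  deviations are floored at 1e-4 to keep weights finite.
* Trigamma inversion: Newton iterations to a relative step below 1e-10,
  with closed-form guards for very large / very small arguments.
* All-zero gene rows are retained (flagged); all-zero samples are an error.
* A design with no residual degrees of freedom is rejected at the
  transformation step; genes with zero residual variance shrink fully to
  the prior.
* MDS warns when the negative eigenvalue mass exceeds 1e-8 of the positive
  mass (non-Euclidean input).
* TOM denominators are asserted positive (guaranteed for adjacencies in
  [0, 1] with unit diagonal).

# Problem sizes used by the test-suite

The suite runs entirely on generated data: the end-to-end recovery uses the
default 2000-gene configuration; the global-null FDR check uses 20
simulations of 2000 genes × 6 interaction contrasts; moderation recovery
uses 5000 simulated variances; module recovery uses 1000 genes with two
50-gene planted modules (modules are kept a small fraction of the
transcriptome because compositional CPM coupling would otherwise induce
spurious between-module correlation); annotation oracles run on 50 random
instances. These sizes are the package's chosen verification conditions and
complete in about a minute.

# Known limitations

* The static tree cut will split or merge modules differently from dynamic
  cutting on real data; module counts are therefore parameter-dependent.
* The moderation estimator assumes a common residual df across genes within
  a fit (true for the saturated design on complete data).
* Promoter assignment considers `gene` features only; isoform-level TSS
  variation is not modelled.
* The comparative-Ct module assumes perfect (2-fold per cycle)
  amplification efficiency, as the comparative formulas imply; efficiency
  estimation is out of scope.
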