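# thermomem

Plants remember heat. A mild "priming" heat exposure leaves *Arabidopsis*
seedlings better prepared for a later severe "triggering" stress, and part of
that memory is transcriptional: NAC-family transcription factors (among them
ATAF1 and ANAC055) change expression after priming and shape which genes stay
induced or repressed through the memory phase. `thermomem` is an R package,
plus a numbered analysis workflow, that implements the full inference chain
used to dissect this behaviour — from raw qPCR cycle thresholds and RNA-seq
count matrices to a ranked list of candidate direct targets of a
transcription factor — together with a synthetic-data generator that plants a
known truth so every stage can be verified end to end.

## What the pipeline computes

**Comparative-Ct screen** (`compute_expression`, `fold_change_profile`,
`call_differential`, `cluster_profiles`). Expression is 40 − ΔCt with
ΔCt = Ct_gene − Ct_reference per sample, so a log2 fold change between arms
is a difference of arm means; genes are called differentially expressed at
|log2 ratio| ≥ log2(1.5) at any timepoint, and trajectories are clustered by
k-means.

**Differential expression** (`precision_weighted_logcpm`,
`fit_gene_models`, `empirical_bayes_moderate`, `interaction_contrast`,
`decide_global`). Counts become precision-weighted, quantile-normalized
log2-CPM; each gene is fitted by weighted least squares on the saturated
genotype × condition × timepoint design; residual variances are shrunk
toward a scaled-F prior estimated by trigamma moment matching, giving
moderated t statistics

&nbsp;&nbsp;&nbsp;&nbsp;t̃_g = (cᵀβ̂_g) / √(cᵀ(XᵀW_gX)⁻¹c · s̃²_g),
&nbsp;&nbsp;s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g),

for the second-order interaction contrast
(heat − control)_genotype − (heat − control)_WT, with Benjamini-Hochberg
decisions applied globally across all genes and contrasts at FDR 0.05.

**Binding and targets** (`parse_gene_models`, `parse_peaks`, `nearest_tss`,
`promoter_bound_genes`, `discordant_by_genotype`,
`candidate_direct_targets`, `commonality_filter`). A gene is
promoter-bound when a peak overlaps the strand-aware 1-kb window upstream of
its TSS; candidate direct targets are genes significantly up in the
overexpressor *and* down in the knockout (or vice versa), promoter-bound,
and supported at ≥ 2 of the 3 timepoints.

**Co-expression** (`soft_power_scan`, `build_adjacency`,
`topological_overlap`, `detect_modules`, `module_enrichment`). An unsigned
weighted network a_ij = |cor|^β (β = 6 by default, chosen by scale-free
fit), topological-overlap similarity, average-linkage module detection, and
upper-tail hypergeometric enrichment of transcription-factor target sets
per module, BH-adjusted.

**Phenotype** (`chlorophyll`, `normalize_to_control`, `fresh_mass_ratio`,
`recovery_class_summary`). The published chlorophyll absorbance formulas
applied verbatim, control-normalized, plus fresh-mass ratios and
recovery-class proportions.

**Synthetic data** (`sim_config`, `plant_truth`, `simulate_counts`,
`simulate_ct_table`, `simulate_annotation_and_peaks`,
`write_sim_dataset`). Negative-binomial counts over the full factorial
design with planted heat, genotype, and interaction effects (opposite sign
in overexpressor vs knockout), planted co-expression modules, a planted
qPCR panel, and GFF3/narrowPeak files whose target peaks always satisfy —
and whose decoys never satisfy — the promoter rule.

## Worked example

```r
library(thermomem)

cfg   <- sim_config(seed = 1)          # 2000 genes, 50 planted targets
rec   <- recover_targets(cfg)          # simulate -> DE -> binding -> filter
rec$n_candidates                       # 43
c(rec$precision, rec$recall, rec$f1)   # 1.00  0.86  0.92
head(rec$candidates, 3)
#   gene_id direction n_timepoints timepoints
# 1   g0015 repressed            3   0h;1h;4h
# 2   g0052 repressed            3   0h;1h;4h
# 3   g0166 activated            3   0h;1h;4h
```

Of the 50 planted direct targets, 43 are recovered with no false positives:
every candidate is significantly discordant between overexpressor and
knockout at two or more timepoints *and* carries a promoter-proximal peak.
Setting `target_interaction_lfc = 0` in the same configuration yields an
empty candidate list — the filters do not invent targets when none exist.

The same chain, stage by stage with intermediate tables written under
`results/`, is in the numbered scripts:

```sh
Rscript analysis/01_simulate.R      # inputs + planted truth
Rscript analysis/02_qpcr_screen.R   # 40-dCt profiles, 1.5-fold calls, k-means
Rscript analysis/03_diffexpr.R      # weights, moderation, contrasts, BH
Rscript analysis/04_targets.R       # promoter rule, discordance, 2-of-3
Rscript analysis/05_coexpr.R        # power scan, TOM, modules, enrichment
Rscript analysis/06_phenotype.R     # chlorophyll, fresh mass, classes
```

## Layout

```
R/                 implementation (simulation, qpcr, diffexpr, annotation,
                   targets, coexpr, phenotype, pipeline)
analysis/          numbered workflow drivers (write results/)
scripts/           acceptance.R
tests/testthat/    unit, property and end-to-end recovery tests with
                   independent brute-force oracles
vignettes/         methods vignette (model, assumptions, design choices)
inst/extdata/      small synthetic phenotype input tables
```
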