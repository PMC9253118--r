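#!/usr/bin/env Rscript
# Step 1 — generate the synthetic thermomemory data set.
#
# Writes every pipeline input (RNA-seq counts + sample sheet, qPCR Ct table,
# gene models as GFF3, binding peaks as narrowPeak) together with the planted
# truth, under results/sim/. All later steps read from there, so the whole
# workflow is reproducible from this single seed.

library(thermomem)

cfg <- sim_config(seed = 1)
out <- write_sim_dataset(cfg, "results/sim")

cat("Simulated", cfg$n_genes, "genes x", nrow(out$samples), "samples;",
    nrow(out$truth$targets), "planted direct targets,",
    cfg$n_modules, "co-expression modules,",
    nrow(out$truth$peaks), "binding peaks (",
    sum(out$truth$peaks$class == "decoy"), "decoys ).\n")
cat("Planted qPCR panel:", length(out$truth$ct$panel), "genes,",
    length(out$truth$ct$undetectable), "undetectable.\n")
cat("Files written under results/sim/\n")
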