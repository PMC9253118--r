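#!/usr/bin/env Rscript
# Step 6 — phenotype quantifications.
#
# Chlorophyll concentrations from the bundled synthetic absorbance records
# (published coefficient set, dilution-corrected), normalization to each
# genotype's control, fresh-mass ratios, and recovery-class proportions.

library(thermomem)

dir.create("results/phenotype", showWarnings = FALSE, recursive = TRUE)
ext <- function(f) system.file("extdata", f, package = "thermomem")

abs_rec <- read.csv(ext("synthetic_absorbance.csv"))
chl <- cbind(abs_rec[c("sample_id", "genotype", "treatment")],
             chlorophyll(abs_rec$od663, abs_rec$od645,
                         dilution = abs_rec$dilution, fm = abs_rec$fm))
chl$normalized <- normalize_to_control(chl$total_mg_per_g, chl$genotype,
                                       chl$treatment)
write.table(chl, "results/phenotype/chlorophyll.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

mass <- read.csv(ext("synthetic_fresh_mass.csv"))
fm <- fresh_mass_ratio(mass)
write.table(fm, "results/phenotype/fresh_mass_ratio.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

classes <- read.csv(ext("synthetic_recovery_classes.csv"))
rc <- recovery_class_summary(classes)
write.table(rc, "results/phenotype/recovery_classes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Chlorophyll (total, mg/g FM), stressed vs control per genotype:\n")
print(round(tapply(chl$normalized, list(chl$genotype, chl$treatment), mean),
            3))
cat("Fresh-mass ratios:\n")
print(fm[c("genotype", "ratio", "sd", "p")], digits = 3)
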