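#!/usr/bin/env Rscript
# Stage 1: generate the synthetic admixed case-control cohort the rest of
# the workflow analyses. Defaults mirror the target study design: 176 cases
# and 183 controls pre-QC, ~127 candidate SNPs including three small LD
# blocks, predominantly European three-way admixture, SES/education/BMI
# correlated with ancestry, and SES/education/age mildly associated with
# case status (the confounding the RDM stage has to neutralize). Planted
# truths: additive ORs 1.5, 1.9 and 0.5 on three SNPs, OR 1.75 on one
# block haplotype.

library(rdmassoc)

seed <- 20260926L %% 100000L
cfg <- sim_config(seed = seed)
ds <- simulate_dataset(cfg)

paths <- write_dataset(ds, "results/data", prefix = "cohort")
cat("cohort:", length(ds$geno$samples), "samples x",
    ncol(ds$geno$dosage), "SNPs;",
    sum(ds$pheno$status == "case"), "cases /",
    sum(ds$pheno$status == "control"), "controls\n")
cat("missing genotype rate:",
    sprintf("%.2f%%", 100 * mean(is.na(ds$geno$dosage))), "\n")
cat("mean European ancestry:",
    sprintf("%.2f", mean(ds$pheno$anc_eur)), "\n")
cat("files:\n"); for (p in paths) cat(" ", p, "\n")
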