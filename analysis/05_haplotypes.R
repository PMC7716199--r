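#!/usr/bin/env Rscript
# Stage 5: haplotype analysis for genes with SNPs in significant pairwise
# LD (BH within gene). EM haplotype frequencies per group, adjusted
# one-vs-rest association on expected dosages, and the haplotype-level RDM.

library(rdmassoc)

geno <- read_ped_map("results/data/cohort_qc.ped", "results/data/cohort_qc.map")
pheno <- read_covariates("results/data/cohort_covariates.tsv")
genes <- read.table("results/data/cohort_genes.tsv", header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
geno$snps$gene <- genes$gene[match(geno$snps$snp_id, genes$snp_id)]

rc <- run_config(seed = 77001L)
blocks <- ld_gene_screen(geno, rc)
cat("genes with >= 2 SNPs in significant LD:",
    if (length(blocks)) paste(names(blocks), collapse = ", ") else "none", "\n")

ens <- build_ensemble(pheno, rc)
tables <- list()
for (g in names(blocks)) {
  hs <- em_haplotypes(geno, blocks[[g]], pheno, rc)
  ha <- haplotype_association(hs, pheno, rc)
  hr <- haplotype_rdm(geno, blocks[[g]], pheno, ens, rc)
  tab <- haplotype_report(ha, gene = g, rdm = hr)
  tables[[g]] <- tab
  cat("\n", g, " (", paste(blocks[[g]], collapse = "|"), "):\n", sep = "")
  print(tab, digits = 3)
}
out <- do.call(rbind, tables)
write_report(out, "results/table2_style.tsv")
cat("\nwrote results/table2_style.tsv\n")
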