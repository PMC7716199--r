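# Programmatic fixtures shared across test files.

toy_snps <- function(m, gene = NULL) {
  data.frame(snp_id = sprintf("s%03d", seq_len(m)), chrom = "1",
             pos = 1000L * seq_len(m),
             allele_minor = "A", allele_major = "G",
             gene = gene %||% sprintf("g%03d", seq_len(m)),
             stringsAsFactors = FALSE)
}

toy_geno <- function(dosage, gene = NULL) {
  dosage <- as.matrix(dosage)
  genotype_matrix(dosage, toy_snps(ncol(dosage), gene),
                  sprintf("I%03d", seq_len(nrow(dosage))))
}

toy_pheno <- function(n, status = rep(c("case", "control"), length.out = n),
                      age = NULL, ses = NULL, education = NULL) {
  phenotype_table(data.frame(
    sample_id = sprintf("I%03d", seq_len(n)),
    status = status,
    age = age %||% seq(50, 70, length.out = n),
    bmi = seq(22, 30, length.out = n),
    anc_eur = 0.8, anc_afr = 0.1, anc_nat = 0.1,
    ses = ses %||% rep(1:3, length.out = n),
    education = education %||% rep(1:3, length.out = n),
    stringsAsFactors = FALSE))
}

# Write a tiny PED/MAP pair from explicit allele strings.
# geno_rows: character vector, one sample per element, alleles space-separated.
write_toy_ped <- function(geno_rows, snp_ids) {
  dir <- tempfile("pedmap")
  dir.create(dir)
  map <- file.path(dir, "toy.map")
  ped <- file.path(dir, "toy.ped")
  writeLines(sprintf("1\t%s\t0\t%d", snp_ids, seq_along(snp_ids) * 1000L), map)
  writeLines(sprintf("F%02d I%02d 0 0 2 -9 %s", seq_along(geno_rows),
                     seq_along(geno_rows), geno_rows), ped)
  list(ped = ped, map = map)
}

# A small simulated dataset reused by several files (built once per run).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_snps = 20L, seed = 42L)
      cache <<- c(simulate_dataset(cfg), list(config = cfg))
    }
    cache
  }
})
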