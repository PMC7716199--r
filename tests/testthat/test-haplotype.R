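test_that("EM equals direct counting on phase-unambiguous data", {
  # at most one heterozygous site per individual: no phase ambiguity
  dos <- rbind(c(0, 0), c(2, 2), c(1, 0), c(0, 1), c(2, 0), c(2, 2),
               c(0, 0), c(1, 2))
  g <- toy_geno(dos)
  hs <- em_haplotypes(g, c("s001", "s002"))
  counted <- oracle_hap_count(dos)
  expect_equal(hs$freq_pooled[names(counted)], counted, tolerance = 1e-10)
  expect_lte(hs$n_em_iterations, 3L)
  # expected dosages are exact haplotype counts here
  expect_equal(unname(rowSums(hs$dosage)), rep(2, nrow(dos)), tolerance = 1e-9)
})

test_that("the double-heterozygote posterior follows the EM fixed point", {
  # one ambiguous individual among unambiguous 00/00 and 11/11 homozygotes:
  # phase 00|11 must dominate phase 01|10 in its posterior dosages
  dos <- rbind(matrix(rep(c(0, 0), 6), ncol = 2, byrow = TRUE),
               matrix(rep(c(2, 2), 6), ncol = 2, byrow = TRUE),
               c(1, 1))
  g <- toy_geno(dos)
  hs <- em_haplotypes(g, c("s001", "s002"))
  amb <- hs$dosage[13, ]
  expect_gt(amb[["00"]] + amb[["11"]], 1.9)
  expect_lt(amb[["01"]] + amb[["10"]], 0.1)
  expect_equal(sum(amb), 2, tolerance = 1e-8)
})

test_that("EM log-likelihood is nondecreasing and frequencies stay on the simplex", {
  set.seed(61)
  for (r in 1:40) {
    n <- sample(10:40, 1)
    k <- sample(2:4, 1)
    dos <- matrix(rbinom(n * k, 2, runif(1, 0.2, 0.6)), n, k)
    g <- toy_geno(dos)
    hs <- tryCatch(em_haplotypes(g, g$snps$snp_id[1:k]),
                   error = function(e) NULL)
    if (is.null(hs)) next
    expect_true(all(diff(hs$loglik) > -1e-9))
    expect_equal(sum(hs$freq_pooled), 1, tolerance = 1e-8)
    ok <- !is.na(hs$dosage[, 1])
    expect_equal(unname(rowSums(hs$dosage[ok, , drop = FALSE])),
                 rep(2, sum(ok)), tolerance = 1e-8)
  }
})

test_that("two-SNP EM frequencies match the grid-search likelihood oracle", {
  set.seed(62)
  for (r in 1:8) {
    n <- sample(12:30, 1)
    dA <- rbinom(n, 2, runif(1, 0.25, 0.6))
    dB <- rbinom(n, 2, runif(1, 0.25, 0.6))
    if (length(unique(dA)) < 2 || length(unique(dB)) < 2) next
    g <- toy_geno(cbind(dA, dB))
    hs <- em_haplotypes(g, c("s001", "s002"))
    ora <- oracle_hap2_grid(dA, dB)
    f <- setNames(rep(0, 4), c("00", "01", "10", "11"))
    f[names(hs$freq_pooled)] <- hs$freq_pooled
    expect_equal(unname(f), unname(ora$freq), tolerance = 1e-3)
  }
})

test_that("LD measures are symmetric, bounded, and null/complete where expected", {
  set.seed(63)
  n <- 10000
  a <- rbinom(n, 2, 0.3); b <- rbinom(n, 2, 0.4)
  ld0 <- ld_pair(a, b)
  expect_lt(ld0$r2, 0.01)
  ldBA <- ld_pair(b, a)
  expect_equal(ld0$r2, ldBA$r2, tolerance = 1e-9)
  expect_equal(abs(ld0$D), abs(ldBA$D), tolerance = 1e-9)
  # r2 invariant to allele relabeling at one locus
  ld_flip <- ld_pair(2 - a, b)
  expect_equal(ld0$r2, ld_flip$r2, tolerance = 1e-6)

  # complete LD: both SNPs always carried by the same gamete
  g1 <- rbinom(500, 1, 0.4); g2 <- rbinom(500, 1, 0.4)
  ldc <- ld_pair(g1 + g2, g1 + g2)
  expect_equal(ldc$Dprime, 1, tolerance = 1e-6)
  expect_equal(ldc$r2, 1, tolerance = 1e-6)

  expect_error(ld_pair(rep(0, 10), rbinom(10, 2, 0.5)), "monomorphic")
})

test_that("the gene-level LD screen finds simulated blocks and skips independent SNPs", {
  ds <- shared_sim()
  qc <- apply_filters(ds$geno, ds$pheno)
  blocks <- ld_gene_screen(qc$geno)
  expect_true(length(blocks) >= 2L)
  expect_true(all(grepl("blockgene", names(blocks))))
  for (b in blocks) expect_gte(length(b), 2L)
})

test_that("haplotype association recovers direction and group frequencies sum to one", {
  ds <- shared_sim()                   # block1 haplotype 11 planted OR 1.75
  qc <- apply_filters(ds$geno, ds$pheno)
  blocks <- ld_gene_screen(qc$geno)
  hs <- em_haplotypes(qc$geno, blocks[["blockgene01"]], ds$pheno)
  expect_equal(sum(hs$freq_cases), 1, tolerance = 1e-6)
  expect_equal(sum(hs$freq_controls), 1, tolerance = 1e-6)
  expect_equal(sum(hs$freq_cases - hs$freq_controls), 0, tolerance = 1e-6)
  ha <- haplotype_association(hs, ds$pheno)
  expect_equal(ha$or, exp(ha$beta), tolerance = 1e-12)
  risky <- ha[ha$haplotype == "11", ]
  expect_gt(risky$or, 1)
})

test_that("haplotype RDM matches haplotypes across sub-samples and is reproducible", {
  ds <- shared_sim()
  qc <- apply_filters(ds$geno, ds$pheno)
  blocks <- ld_gene_screen(qc$geno)
  rc <- run_config(n_subsamples = 30L, seed = 64L)
  ens <- build_ensemble(ds$pheno, rc)
  r1 <- haplotype_rdm(qc$geno, blocks[["blockgene01"]], ds$pheno, ens, rc)
  r2 <- haplotype_rdm(qc$geno, blocks[["blockgene01"]], ds$pheno, ens, rc)
  expect_identical(r1, r2)
  expect_true(all(r1$fraction_significant >= 0 & r1$fraction_significant <= 1,
                  na.rm = TRUE))
  expect_gte(r1$fraction_significant[r1$unit == "11"],
             r1$fraction_significant[r1$unit == "10"] - 0.2)
})
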