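test_that("MAF folds to the minor side and excludes missing genotypes", {
  expect_equal(as.numeric(compute_maf(c(0, 1, 2))), 0.5)
  m <- compute_maf(c(0, 0, 1, NA))
  expect_equal(as.numeric(m), 1 / 6)
  expect_false(attr(m, "flipped"))
  expect_equal(as.numeric(compute_maf(c(0, 0, 0))), 0)
  f <- compute_maf(c(2, 2, 1))
  expect_equal(as.numeric(f), 1 / 6)
  expect_true(attr(f, "flipped"))
  expect_error(compute_maf(c(NA, NA)), "missing")
})

test_that("HWE exact p-values match the enumeration oracle on hand-picked tables", {
  # monomorphic tables are consistent with HWE by construction
  expect_equal(hwe_exact_test(0, 0, 25), 1.0)
  expect_equal(hwe_exact_test(25, 0, 0), 1.0)
  # n = 12, minor count 4: conditional support {0, 2, 4} heterozygotes
  expect_equal(hwe_exact_test(9, 2, 1), oracle_hwe(9, 2, 1), tolerance = 1e-12)
  # label symmetry
  expect_equal(hwe_exact_test(9, 2, 1), hwe_exact_test(1, 2, 9))
  expect_equal(hwe_exact_test(57, 14, 50), oracle_hwe(57, 14, 50),
               tolerance = 1e-12)
})

test_that("HWE exact p-values are conservative under true equilibrium", {
  set.seed(21)
  n <- 120L
  reps <- 4000L
  p <- 0.2
  g <- matrix(rbinom(2L * n * reps, 1L, p), ncol = 2L)
  d <- g[, 1] + g[, 2]
  dm <- matrix(d, n, reps)
  pv <- vapply(seq_len(reps), function(r) {
    x <- dm[, r]
    hwe_exact_test(sum(x == 2L), sum(x == 1L), sum(x == 0L))
  }, numeric(1))
  expect_lte(mean(pv <= 0.05), 0.06)
})

test_that("QC filters apply in the documented order and report attrition", {
  # 10 samples x 5 SNPs; SNP s002 40% missing; samples I001-I002 miss most of
  # the remaining SNPs; SNP s005 is monomorphic (MAF 0)
  set.seed(22)
  d <- matrix(rbinom(50, 2, 0.4), 10, 5)
  d[1:4, 2] <- NA                      # s002 call rate 0.6 -> step 1
  d[1, 1] <- NA                        # I001 call rate 3/4 on surviving SNPs
  d[2, 3] <- NA                        # I002 likewise
  d[, 5] <- 0L                         # s005 MAF 0 -> step 3
  g <- toy_geno(d)
  ph <- toy_pheno(10)
  qc <- apply_filters(g, ph, run_config())
  expect_equal(sort(setdiff(g$snps$snp_id, qc$geno$snps$snp_id)),
               c("s002", "s005"))
  expect_equal(setdiff(g$samples, qc$geno$samples), c("I001", "I002"))
  expect_equal(unname(qc$report$summary["snps_fail_call"]), 1)
  expect_equal(unname(qc$report$summary["snps_fail_maf"]), 1)
  expect_equal(unname(qc$report$summary["samples_fail_call"]), 2)
  # HWE is reported, never used for exclusion
  expect_true(all(c("hwe_p_controls", "hwe_q_controls") %in%
                    names(qc$report$hwe)))
})

test_that("zero thresholds are the identity and filtering is idempotent and order-invariant", {
  ds <- shared_sim()
  cfg0 <- run_config(maf_min = 0, snp_call_min = 0, sample_call_min = 0)
  qc0 <- apply_filters(ds$geno, ds$pheno, cfg0)
  expect_identical(qc0$geno$dosage, ds$geno$dosage)

  cfg <- run_config()
  qc1 <- apply_filters(ds$geno, ds$pheno, cfg)
  qc2 <- apply_filters(qc1$geno, ds$pheno, cfg)
  expect_identical(qc2$geno$dosage, qc1$geno$dosage)

  perm <- rev(seq_along(ds$geno$samples))
  gp <- subset_genotypes(ds$geno, samples = perm)
  qcp <- apply_filters(gp, ds$pheno, cfg)
  expect_setequal(qcp$geno$samples, qc1$geno$samples)
  expect_setequal(qcp$geno$snps$snp_id, qc1$geno$snps$snp_id)
})
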