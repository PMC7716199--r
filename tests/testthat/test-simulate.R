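test_that("Balding-Nichols frequencies have the prescribed moments", {
  set.seed(11)
  fr <- sample_ancestral_freqs(30000L, fst = 0.1, base_maf_range = c(0.3, 0.3))
  draws <- as.vector(fr$pops)
  n <- length(draws)
  # Beta(p(1-F)/F, (1-p)(1-F)/F): mean p, variance F p (1-p)
  se_mean <- sqrt(0.1 * 0.3 * 0.7 / n)
  expect_lt(abs(mean(draws) - 0.3), 3 * se_mean)
  expect_lt(abs(var(draws) - 0.1 * 0.3 * 0.7), 0.15 * 0.1 * 0.3 * 0.7)
})

test_that("fst near zero collapses population frequencies onto the ancestral value", {
  set.seed(12)
  fr <- sample_ancestral_freqs(200L, fst = 1e-6, base_maf_range = c(0.2, 0.4))
  expect_lt(max(abs(fr$pops - fr$base)), 0.02)
})

test_that("ancestry proportions sum to one with the Dirichlet mean", {
  set.seed(13)
  a <- sample_ancestry(20000L, c(16, 2, 2))
  expect_equal(rowSums(a), rep(1, nrow(a)), tolerance = 1e-12)
  expect_equal(colMeans(a), c(16, 2, 2) / 20, tolerance = 0.01)
})

test_that("pure-ancestry samples draw gametes at that population's frequency", {
  set.seed(14)
  n <- 20000L
  anc <- matrix(c(1, 0, 0), n, 3, byrow = TRUE)
  pf <- matrix(c(0.2, 0.8, 0.5), 1, 3)
  g <- simulate_genotypes(anc, pf)
  maf <- mean(g$dosage[, 1]) / 2
  expect_lt(abs(maf - 0.2), 3 * sqrt(0.2 * 0.8 / (2 * n)))
})

test_that("admixed MAF matches the ancestry-weighted mixture frequency", {
  set.seed(15)
  n <- 5000L
  anc <- sample_ancestry(n, c(16, 2, 2))
  set.seed(16)
  fr <- sample_ancestral_freqs(40L, 0.1)
  g <- simulate_genotypes(anc, fr$pops)
  expected <- colMeans(anc %*% t(fr$pops))
  got <- colMeans(g$dosage) / 2
  tol <- 3 * sqrt(expected * (1 - expected) / (2 * n))
  expect_true(all(abs(got - expected) < tol + 0.01))
})

test_that("a two-haplotype block yields complete LD", {
  set.seed(17)
  n <- 10000L
  anc <- sample_ancestry(n, c(16, 2, 2))
  bf <- list(matrix(0.5, 2, 3, dimnames = list(c("00", "11"), NULL)))
  g <- simulate_genotypes(anc, NULL, bf)
  ld <- ld_pair(g$dosage[, 1], g$dosage[, 2])
  expect_gt(ld$r2, 0.999)
  expect_gt(ld$Dprime, 0.999)
  # every double heterozygote is truly 00/11 phase
  dh <- g$dosage[, 1] == 1L & g$dosage[, 2] == 1L
  expect_true(all(g$block_haplotypes[[1]][dh, ] %in% c("00", "11")))
})

test_that("identical seeds give bitwise-identical datasets on disk", {
  cfg <- sim_config(n_snps = 10L, n_cases = 40L, n_controls = 40L, seed = 99L)
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(simulate_dataset(cfg), d1)
  write_dataset(simulate_dataset(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("planted effects shift case genotype distributions; nulls do not", {
  ds <- shared_sim()
  scan <- run_scan(ds$geno, ds$pheno)
  strong <- scan[scan$snp_id == "snp002", ]       # planted OR 1.9
  expect_lt(strong$p_adj_model, 0.05)
  expect_gt(strong$or_adj, 1)
  prot <- scan[scan$snp_id == "snp003", ]         # planted OR 0.5
  expect_lt(prot$or_adj, 1)
})

test_that("confounder bias makes SES imbalanced between cases and controls", {
  # the imbalance the RDM matching exists to remove
  set.seed(18)
  hits <- 0L
  for (r in 1:5) {
    cfg <- sim_config(n_snps = 5L, effects = NULL,
                      confounder_status_bias = c(ses = 0.4, education = 0,
                                                 age = 0),
                      seed = 500L + r)
    ds <- simulate_dataset(cfg)
    p <- suppressWarnings(stats::chisq.test(
      table(ds$pheno$ses, ds$pheno$status), correct = FALSE)$p.value)
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits, 3L)
})

test_that("missingness injection matches the requested rates and hits designated SNPs", {
  ds <- shared_sim()
  g0 <- genotype_matrix(
    matrix(1L, 300, 10), toy_snps(10), sprintf("P%03d", 1:300))
  set.seed(19)
  g1 <- inject_missingness(g0, 0, 0)
  expect_identical(g1$dosage, g0$dosage)
  g2 <- inject_missingness(g0, 0.05, 0)
  n_miss <- sum(is.na(g2$dosage))
  expected <- 0.05 * 3000
  expect_lt(abs(n_miss - expected), 3 * sqrt(3000 * 0.05 * 0.95))
  # designated high-missingness SNPs fail the 90% call-rate filter
  fails <- replicate(10, {
    g3 <- inject_missingness(g0, 0.01, 0, elevated_snps = c("s001", "s002", "s003"),
                             elevated_rate_snp = 0.15)
    sum(colMeans(!is.na(g3$dosage))[1:3] < 0.9)
  })
  expect_gte(mean(fails), 2.9 - 3 * sd(fails) / sqrt(10))
  expect_gte(mean(fails), 2.0)
})
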