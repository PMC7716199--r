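test_that("sub-samples are uniform draws without replacement", {
  ph <- toy_pheno(60)
  cases <- ph$sample_id[ph$status == "case"]
  ctrls <- ph$sample_id[ph$status == "control"]
  set.seed(41)
  s <- draw_subsample(cases, ctrls, length(cases), 10)
  expect_setequal(s$cases, cases)                 # exhaustive draw
  expect_equal(length(unique(s$controls)), 10)

  set.seed(42)
  counts <- table(factor(unlist(
    replicate(4000, draw_subsample(cases, ctrls, 10, 5)$cases)),
    levels = cases))
  expected <- 4000 * 10 / length(cases)
  sd3 <- 3 * sqrt(4000 * (10 / length(cases)) * (1 - 10 / length(cases)))
  expect_true(all(abs(counts - expected) < sd3))

  expect_error(draw_subsample(cases, ctrls, length(cases) + 1, 5), "cases")

  set.seed(7); a <- draw_subsample(cases, ctrls, 10, 10)
  set.seed(7); b <- draw_subsample(cases, ctrls, 10, 10)
  expect_identical(a, b)
})

test_that("balance check accepts exchangeable covariates and rejects gross imbalance", {
  set.seed(43)
  n <- 208
  make_ph <- function(age_shift = 0) {
    phenotype_table(data.frame(
      sample_id = sprintf("I%03d", 1:n),
      status = rep(c("case", "control"), c(100, 108)),
      age = c(rnorm(100, 60 + age_shift, 8), rnorm(108, 60, 8)),
      bmi = rnorm(n, 26, 4),
      anc_eur = 0.8, anc_afr = 0.1, anc_nat = 0.1,
      ses = sample(1:3, n, TRUE), education = sample(1:3, n, TRUE)))
  }
  sub <- list(cases = sprintf("I%03d", 1:100),
              controls = sprintf("I%03d", 101:208))
  acc <- replicate(200, {
    ph <- make_ph()
    balance_check(sub, ph)$accept
  })
  expect_gt(mean(acc), 0.8)          # three near-independent 5% checks

  acc_bad <- replicate(50, balance_check(sub, make_ph(16))$accept)
  expect_lt(mean(acc_bad), 0.05)     # age shifted by +2 SD

  ph_const <- make_ph()
  ph_const$ses <- 2L
  expect_warning(b <- balance_check(sub, ph_const), "constant")
  expect_equal(unname(b$p[["ses"]]), 1)
})

test_that("ensembles are reproducible and infeasible matching exhausts the budget", {
  ds <- shared_sim()
  cfg <- run_config(n_subsamples = 25L, seed = 44L)
  e1 <- build_ensemble(ds$pheno, cfg)
  e2 <- build_ensemble(ds$pheno, cfg)
  expect_identical(e1$subsamples, e2$subsamples)
  expect_equal(e1$n_accepted, 25L)
  expect_true(all(e1$balance_p >= cfg$balance_alpha))

  # SES fully determined by status: no sub-sample can balance it
  ph <- toy_pheno(300, status = rep(c("case", "control"), each = 150),
                  ses = rep(c(3, 1), each = 150),
                  age = rnorm(300, 60, 8))
  cfg2 <- run_config(n_subsamples = 3L, n_cases_sub = 100L,
                     n_controls_sub = 100L, seed = 45L)
  expect_error(build_ensemble(ph, cfg2), "budget exhausted")
})

test_that("RDM power is monotone in the planted effect and summaries are coherent", {
  base <- 600L
  fracs <- vapply(c(1.0, 1.5, 2.2), function(or) {
    set.seed(46)
    cfg <- sim_config(n_snps = 4L, ld_blocks = list(),
                      effects = data.frame(unit = "snp", id = "snp001",
                                           log_or = log(or)),
                      confounder_status_bias = c(ses = 0.3, education = 0,
                                                 age = 0.02),
                      seed = base + round(100 * or))
    ds <- simulate_dataset(cfg)
    qc <- apply_filters(ds$geno, ds$pheno)
    rc <- run_config(n_subsamples = 60L, seed = 47L)
    ens <- build_ensemble(ds$pheno, rc)
    rdm <- rdm_scan(qc$geno, ds$pheno, ens, rc)
    expect_true(all(rdm$n_evaluated <= 60L))
    expect_equal(rdm$fraction_significant,
                 rdm$n_significant / rdm$n_evaluated)
    rdm$fraction_significant[rdm$unit == "snp001"]
  }, numeric(1))
  expect_true(all(diff(fracs) >= -0.05))
  expect_gt(fracs[3], 0.5)           # a strong effect is kept
  expect_lt(fracs[1], 0.3)           # the null is not
})

test_that("a SNP monomorphic within sub-samples is never evaluated", {
  ds <- shared_sim()
  g <- ds$geno
  g$dosage[, 1] <- 0L                # monomorphic everywhere
  g <- genotype_matrix(g$dosage, g$snps, g$samples)
  rc <- run_config(n_subsamples = 10L, seed = 48L)
  ens <- build_ensemble(ds$pheno, rc)
  rdm <- rdm_scan(g, ds$pheno, ens, rc)
  r <- rdm[rdm$unit == "snp001", ]
  expect_equal(r$n_evaluated, 0L)
  expect_false(r$keep)
  expect_true(is.na(r$or_median))
})

test_that("matching shrinks the pooled case-control age gap relative to the full sample", {
  set.seed(49)
  cfg <- sim_config(n_snps = 4L, ld_blocks = list(), effects = NULL,
                    confounder_status_bias = c(ses = 0, education = 0,
                                               age = 0.05),
                    seed = 490L)
  ds <- simulate_dataset(cfg)
  full_gap <- abs(mean(ds$pheno$age[ds$pheno$status == "case"]) -
                  mean(ds$pheno$age[ds$pheno$status == "control"])) /
    sd(ds$pheno$age)
  rc <- run_config(n_subsamples = 100L, seed = 50L)
  ens <- build_ensemble(ds$pheno, rc)
  gaps <- vapply(ens$subsamples, function(s) {
    i <- match(s$cases, ds$pheno$sample_id)
    j <- match(s$controls, ds$pheno$sample_id)
    mean(ds$pheno$age[i]) - mean(ds$pheno$age[j])
  }, numeric(1))
  pooled_gap <- abs(mean(gaps)) / sd(ds$pheno$age)
  expect_lt(pooled_gap, full_gap)
})
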