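test_that("allelic test matches the closed-form 2x2 chi-square and OR", {
  # cases: 30 minor / 170 major; controls: 15 / 185
  status <- rep(c("case", "control"), each = 100)
  d_case <- c(rep(2, 5), rep(1, 20), rep(0, 75))
  d_ctrl <- c(rep(2, 1), rep(1, 13), rep(0, 86))
  res <- allelic_test(c(d_case, d_ctrl), status)
  expect_equal(res$or_allelic, (30 * 185) / (170 * 15), tolerance = 1e-12)
  expect_equal(res$chi2, oracle_chi2_2x2(30, 170, 15, 185), tolerance = 1e-12)
  expect_equal(res$p, stats::pchisq(res$chi2, 1, lower.tail = FALSE))
})

test_that("allelic test is symmetric: equal frequencies give the null, label swap inverts the OR", {
  status <- rep(c("case", "control"), each = 50)
  d <- rep(c(0, 1, 2, 1, 0), 20)
  res <- allelic_test(c(d[1:50], d[1:50]), status)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)
  expect_equal(res$or_allelic, 1)

  set.seed(31)
  d2 <- rbinom(100, 2, 0.3)
  a <- allelic_test(d2, status)
  b <- allelic_test(d2, rev(status))
  expect_equal(a$or_allelic, 1 / b$or_allelic, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("IRLS matches the Newton-Raphson oracle on a fixed 12-row dataset", {
  X <- cbind(1,
             c(0, 1, 2, 0, 1, 2, 0, 1, 2, 0, 1, 2),
             c(-0.8, 1.4, -1.3, 0.1, 1.7, -0.6, -0.5, -0.6, -0.3, 0.1, 1.2, -0.8))
  colnames(X) <- c("int", "dosage", "cov")
  y <- c(0, 1, 1, 1, 1, 0, 0, 1, 1, 0, 1, 1)
  fit <- fit_logistic(y, X)
  ora <- oracle_nr_logistic(y, X)
  expect_equal(unname(fit$beta), ora$beta, tolerance = 1e-8)
  expect_equal(unname(fit$se), ora$se, tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("IRLS equals the oracle fit on random small datasets", {
  set.seed(32)
  for (r in 1:25) {
    n <- sample(25:60, 1)
    X <- cbind(1, matrix(rnorm(n * 2), n, 2), rbinom(n, 2, runif(1, 0.2, 0.5)))
    y <- rbinom(n, 1, plogis(X %*% c(0.2, 0.5, -0.3, 0.4)))
    if (length(unique(y)) < 2) next
    fit <- fit_logistic(y, X)
    if (fit$separated) next
    ora <- oracle_nr_logistic(y, X)
    expect_equal(unname(fit$beta), ora$beta, tolerance = 1e-8)
    expect_equal(unname(fit$se), ora$se, tolerance = 1e-8)
  }
})

test_that("translating a covariate only moves the intercept", {
  set.seed(33)
  n <- 300
  age <- rnorm(n, 60, 8)
  d <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(-0.5 + 0.3 * d))
  X1 <- cbind(int = 1, age = age, dosage = d)
  X2 <- cbind(int = 1, age = age + 100, dosage = d)
  f1 <- fit_logistic(y, X1)
  f2 <- fit_logistic(y, X2)
  expect_equal(f1$beta[["dosage"]], f2$beta[["dosage"]], tolerance = 1e-10)
  expect_equal(f1$beta[["age"]], f2$beta[["age"]], tolerance = 1e-10)
})

test_that("separation is flagged, not fatal, and rank deficiency names the column", {
  y <- rep(c(0, 1), each = 10)
  X <- cbind(int = 1, dosage = c(rep(0, 10), rep(2, 10)))
  fit <- fit_logistic(y, X)
  expect_true(fit$separated)
  expect_true(all(is.na(fit$p)))
  X2 <- cbind(int = 1, a = rnorm(20), b = 0)
  expect_error(fit_logistic(y, X2), "b")
})

test_that("BH step-up matches hand computations and preserves NA/order", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.005, 0.009, 0.05, 0.5)),
               c(0.018, 0.018, 0.05 * 4 / 3, 0.5), tolerance = 1e-12)
  q <- bh_fdr(c(0.5, NA, 0.005, 0.009, 0.05))
  expect_true(is.na(q[2]))
  expect_equal(q[-2], c(0.5, 0.018, 0.018, 0.05 * 4 / 3), tolerance = 1e-12)
  # monotone in the sorted-p order
  set.seed(34)
  p <- runif(50)
  q2 <- bh_fdr(p)
  expect_true(all(diff(q2[order(p)]) > -1e-12))
  expect_true(all(q2 >= p))
})

test_that("the adjusted scan keeps type-I error near nominal and reports consistent columns", {
  set.seed(35)
  cfg <- sim_config(n_snps = 60L, effects = NULL, ld_blocks = list(),
                    confounder_status_bias = c(ses = 0, education = 0, age = 0),
                    seed = 360L)
  ds <- simulate_dataset(cfg)
  scan <- run_scan(ds$geno, ds$pheno)
  expect_equal(nrow(scan), 60L)
  expect_equal(scan$or_adj, exp(scan$beta), tolerance = 1e-12)
  expect_equal(scan$ci95_low, exp(scan$beta - 1.96 * scan$se), tolerance = 1e-12)
  expect_true(all(scan$q_fdr >= scan$p_adj_model - 1e-12, na.rm = TRUE))
  expect_true(all(scan$n_used <= length(ds$geno$samples)))
  # null panel: rejection rate compatible with Binomial(60, 0.05)
  expect_lte(sum(scan$p_adj_model < 0.05, na.rm = TRUE), 9)
  # allelic and adjusted tests mostly agree on rejection under the null
  agree <- mean((scan$allelic_p < 0.05) == (scan$p_adj_model < 0.05),
                na.rm = TRUE)
  expect_gte(agree, 0.9)
})
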