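# Independent reference implementations used as oracles. These deliberately
# take different computational routes than the package code they check.

# Hardy-Weinberg exact test via the classic upward/downward probability
# recurrence (the package enumerates log-factorials instead).
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n1 <- 2L * min(n_AA, n_aa) + n_Aa
  if (n1 == 0L) return(1.0)
  hs <- seq.int(n1 %% 2L, n1, by = 2L)
  prob <- numeric(length(hs))
  prob[1L] <- 1
  for (i in seq_along(hs)[-1L]) {
    h <- hs[i - 1L]
    a <- (n1 - h) / 2          # minor homozygotes at h
    b <- n - a - h             # major homozygotes at h
    prob[i] <- prob[i - 1L] * 4 * a * b / ((h + 2) * (h + 1))
  }
  prob <- prob / sum(prob)
  obs <- prob[match(n_Aa, hs)]
  min(1, sum(prob[prob <= obs * (1 + 1e-7)]))
}

# Logistic regression by an explicit Newton-Raphson loop (gradient/Hessian
# assembled element-wise, solved with qr.solve).
oracle_nr_logistic <- function(y, X, tol = 1e-12, max_iter = 200L) {
  X <- as.matrix(X)
  beta <- rep(0, ncol(X))
  loglik <- function(b) {
    eta <- as.vector(X %*% b)
    sum(y * eta - log(1 + exp(eta)))
  }
  ll0 <- loglik(beta)
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- exp(eta) / (1 + exp(eta))
    grad <- t(X) %*% (y - mu)
    W <- diag(as.vector(pmax(mu * (1 - mu), 1e-10)), nrow(X))
    H <- t(X) %*% W %*% X
    delta <- qr.solve(H, grad)
    # damped Newton: halve until the likelihood does not decrease
    lam <- 1
    while (lam > 1e-8 && loglik(beta + lam * delta) < ll0 - 1e-12) lam <- lam / 2
    beta <- beta + lam * delta
    ll0 <- loglik(beta)
    if (max(abs(lam * delta)) < tol) break
  }
  eta <- as.vector(X %*% beta)
  mu <- exp(eta) / (1 + exp(eta))
  H <- t(X) %*% diag(as.vector(mu * (1 - mu)), nrow(X)) %*% X
  list(beta = as.vector(beta), se = unname(sqrt(diag(solve(H)))))
}

# Two-SNP haplotype MLE by 1-D grid search: single-locus allele frequencies
# are fixed at their observed values (they are directly observed), leaving
# the frequency of the minor-minor haplotype as the only free parameter.
# The likelihood is evaluated from first principles by summing over ordered
# gamete pairs.
oracle_hap2_grid <- function(dosA, dosB, step = 1e-4) {
  pA <- sum(dosA) / (2 * length(dosA))
  pB <- sum(dosB) / (2 * length(dosB))
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  grid <- seq(lo, hi, by = step)
  if (length(grid) == 0L || grid[length(grid)] < hi) grid <- c(grid, hi)
  # haplotype frequencies as vectors over the grid of p11 values
  f <- list("11" = grid, "10" = pA - grid, "01" = pB - grid,
            "00" = 1 - pA - pB + grid)
  f <- lapply(f, pmax, 0)
  # genotype probabilities from first principles: sum over ordered gamete pairs
  cnt <- table(factor(dosA, levels = 0:2), factor(dosB, levels = 0:2))
  ll <- 0
  for (gA in 0:2) for (gB in 0:2) {
    if (cnt[gA + 1L, gB + 1L] == 0L) next
    pr <- 0
    for (a1 in 0:1) for (a2 in 0:1) for (b1 in 0:1) for (b2 in 0:1) {
      if (a1 + a2 == gA && b1 + b2 == gB)
        pr <- pr + f[[paste0(a1, b1)]] * f[[paste0(a2, b2)]]
    }
    ll <- ll + cnt[gA + 1L, gB + 1L] * log(pr)
  }
  best <- which.max(ll)
  list(freq = c("00" = f[["00"]][best], "01" = f[["01"]][best],
                "10" = f[["10"]][best], "11" = f[["11"]][best]),
       loglik = ll[best])
}

# Direct haplotype counting on phase-unambiguous data (at most one
# heterozygous site per individual).
oracle_hap_count <- function(dos) {
  n <- nrow(dos); k <- ncol(dos)
  counts <- list()
  for (i in seq_len(n)) {
    g <- dos[i, ]
    het <- which(g == 1L)
    stopifnot(length(het) <= 1L)
    h1 <- as.integer(g == 2L); h2 <- h1
    if (length(het)) { h1[het] <- 1L; h2[het] <- 0L }
    for (h in c(paste(h1, collapse = ""), paste(h2, collapse = ""))) {
      counts[[h]] <- (counts[[h]] %||% 0) + 1
    }
  }
  unlist(counts) / (2 * n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Monte-Carlo power of the arcsine-scale two-proportion z test.
oracle_mc_power <- function(h, alpha, n1, n2, p1 = 0.5, nsim = 1e5) {
  p2 <- sin(asin(sqrt(p1)) - h / 2)^2
  x1 <- stats::rbinom(nsim, n1, p1)
  x2 <- stats::rbinom(nsim, n2, p2)
  z <- (2 * asin(sqrt(x1 / n1)) - 2 * asin(sqrt(x2 / n2))) /
    sqrt(1 / n1 + 1 / n2)
  mean(abs(z) > stats::qnorm(1 - alpha / 2))
}

# Pearson chi-square on a 2x2 table via the ad-bc closed form.
oracle_chi2_2x2 <- function(a, b, c0, d) {
  n <- a + b + c0 + d
  n * (a * d - b * c0)^2 / ((a + b) * (c0 + d) * (a + c0) * (b + d))
}
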