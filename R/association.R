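#' Allelic (allele-count) association test
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2 table of
#' minor/major allele counts by case/control. The allelic odds ratio gets the
#' Haldane-Anscombe +0.5 correction in every cell iff any cell is zero.
#'
#' @param dosages minor-allele dosages (0/1/2, NA allowed).
#' @param status factor with levels `control`, `case` (or coercible).
#' @return list with `chi2`, `p`, `or_allelic` and the allele-count `table`.
#' @export
allelic_test <- function(dosages, status) {
  st <- as.factor(status)
  ok <- !is.na(dosages) & !is.na(st)
  d <- dosages[ok]; st <- st[ok]
  case <- st == "case"
  if (!any(case) || !any(!case))
    stop("allelic test needs non-missing genotypes in both groups")
  a <- sum(d[case]); b <- 2 * sum(case) - a          # case minor / major
  cc <- sum(d[!case]); dd <- 2 * sum(!case) - cc     # control minor / major
  tab <- matrix(c(a, cc, b, dd), 2L, 2L,
                dimnames = list(c("case", "control"), c("minor", "major")))
  n <- sum(tab)
  er <- outer(rowSums(tab), colSums(tab)) / n
  if (any(er == 0)) {
    chi2 <- 0; p <- 1
  } else {
    chi2 <- sum((tab - er)^2 / er)
    p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  }
  sh <- if (any(tab == 0)) 0.5 else 0
  or <- ((a + sh) * (dd + sh)) / ((b + sh) * (cc + sh))
  list(chi2 = chi2, p = p, or_allelic = or, table = tab)
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood binomial-logit fit. Convergence when the largest score
#' component is below `tol_score` or the relative log-likelihood change is
#' below `tol_ll`, capped at `max_iter` iterations. Standard errors come from
#' the inverse observed information at the optimum. Complete separation is
#' flagged (any |beta| > 15 without convergence) and yields `NA` p-values
#' rather than an error.
#'
#' @param y 0/1 response.
#' @param X design matrix (include the intercept column yourself).
#' @param max_iter,tol_score,tol_ll convergence controls.
#' @param check_rank verify the design is full rank up front (a singular
#'   information matrix still fails safely when `FALSE`; internal per-SNP
#'   loops disable the check for speed).
#' @return list: `beta`, `se`, `z`, `p` (two-sided Wald), `loglik`,
#'   `iterations`, `converged`, `separated`.
#' @export
fit_logistic <- function(y, X, max_iter = 50L, tol_score = 1e-8,
                         tol_ll = 1e-10, check_rank = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) stop("outcome has a single class")
  if (check_rank) {
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      dep <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
      stop("design matrix is rank deficient; collinear column(s): ",
           paste(dep, collapse = ", "))
    }
  }
  p <- ncol(X)
  beta <- numeric(p)
  for (j in seq_len(p)) {                    # start intercept at logit(ybar)
    xj <- X[, j]
    if (xj[1L] != 0 && all(xj == xj[1L])) {
      beta[j] <- stats::qlogis(mean(y)) / xj[1L]
      break
    }
  }
  ll_of <- function(eta)
    sum(y * eta - log1p(exp(-abs(eta))) - pmax(eta, 0))
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  ll_old <- ll_of(eta)
  converged <- FALSE
  score <- crossprod(X, y - mu)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    if (max(abs(score)) < tol_score) { converged <- TRUE; break }
    w <- mu * (1 - mu)
    w[w < 1e-12] <- 1e-12
    info <- crossprod(X * w, X)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    # step-halving keeps the likelihood ascent monotone near separation
    for (h in 0:5) {
      cand <- beta + drop(step) / 2^h
      eta <- drop(X %*% cand)
      ll_new <- ll_of(eta)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
    }
    beta <- cand
    mu <- 1 / (1 + exp(-eta))
    score <- crossprod(X, y - mu)
    if (abs(ll_new - ll_old) < tol_ll * (abs(ll_old) + 1e-10)) {
      ll_old <- ll_new
      converged <- TRUE
      break
    }
    ll_old <- ll_new
  }
  separated <- any(abs(beta) > 15)
  if (separated) converged <- FALSE
  w <- mu * (1 - mu)
  w[w < 1e-12] <- 1e-12
  info <- crossprod(X * w, X)
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) rep(NA_real_, p))
  z <- drop(beta) / se
  pval <- 2 * stats::pnorm(-abs(z))
  if (separated) pval[] <- NA_real_
  names(beta) <- colnames(X)
  list(beta = drop(beta), se = se, z = z, p = pval, loglik = ll_old,
       iterations = it, converged = converged, separated = separated)
}

adjust_design <- function(pheno, rows = seq_len(nrow(pheno))) {
  cbind(`(Intercept)` = 1,
        age = pheno$age[rows],
        bmi = pheno$bmi[rows],
        anc_eur = pheno$anc_eur[rows])
}

#' Per-SNP association scan
#'
#' For every SNP: the allelic test, plus additive logistic regression of
#' case status on minor-allele dosage adjusted for age, BMI and the European
#' ancestry proportion (a single ancestry proportion avoids the simplex
#' collinearity). Complete cases per SNP; BH FDR over all tested SNPs; rows
#' ordered by genomic position. A failing SNP is flagged, never fatal to the
#' scan.
#'
#' @param geno a QC'd [genotype_matrix()].
#' @param pheno matching `phenotype_table`.
#' @param config a [run_config()].
#' @return data.frame, one row per SNP: group MAFs, allelic chi2/p/OR,
#'   adjusted `beta`, `se`, `or_adj`, `ci95_low`, `ci95_high`,
#'   `p_adj_model`, `q_fdr` (BH over `p_adj_model`), `n_used`, `note`.
#' @export
run_scan <- function(geno, pheno, config = run_config()) {
  idx <- match(geno$samples, pheno$sample_id)
  if (anyNA(idx)) stop("samples missing from the phenotype table")
  ph <- pheno[idx, ]
  y <- as.integer(ph$status == "case")
  base_ok <- stats::complete.cases(ph[, c("age", "bmi", "anc_eur")])
  m <- ncol(geno$dosage)
  out <- vector("list", m)
  for (j in seq_len(m)) {
    d <- geno$dosage[, j]
    snp <- geno$snps[j, ]
    row <- data.frame(
      gene = if ("gene" %in% names(snp)) snp$gene else NA_character_,
      snp_id = snp$snp_id, chrom = snp$chrom, pos = snp$pos,
      maf_controls = NA_real_, maf_cases = NA_real_,
      allelic_chi2 = NA_real_, allelic_p = NA_real_, or_allelic = NA_real_,
      beta = NA_real_, se = NA_real_, or_adj = NA_real_,
      ci95_low = NA_real_, ci95_high = NA_real_, p_adj_model = NA_real_,
      n_used = 0L, note = "", stringsAsFactors = FALSE)
    res <- tryCatch({
      ctrl <- d[ph$status == "control"]; case <- d[ph$status == "case"]
      row$maf_controls <- as.numeric(compute_maf(ctrl))
      row$maf_cases <- as.numeric(compute_maf(case))
      at <- allelic_test(d, ph$status)
      row$allelic_chi2 <- at$chi2; row$allelic_p <- at$p
      row$or_allelic <- at$or_allelic
      use <- base_ok & !is.na(d)
      X <- cbind(adjust_design(ph, which(use)), dosage = d[use])
      fit <- fit_logistic(y[use], X)
      b <- fit$beta[["dosage"]]; s <- fit$se[[ncol(X)]]
      row$beta <- b; row$se <- s
      row$or_adj <- exp(b)
      row$ci95_low <- exp(b - 1.96 * s); row$ci95_high <- exp(b + 1.96 * s)
      row$p_adj_model <- fit$p[[ncol(X)]]
      row$n_used <- sum(use)
      if (fit$separated) row$note <- "separation"
      row
    }, error = function(e) { row$note <- conditionMessage(e); row })
    out[[j]] <- res
  }
  res <- do.call(rbind, out)
  chrom_num <- suppressWarnings(as.numeric(res$chrom))
  res <- res[order(is.na(chrom_num), chrom_num, res$chrom, res$pos), ]
  res$q_fdr <- bh_fdr(res$p_adj_model)
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH with monotonicity enforcement, aligned to the input order.
#' `NA` entries stay `NA` and do not count toward the number of tests.
#'
#' @param pvalues numeric vector in \[0, 1\] (NAs allowed).
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  q <- rep(NA_real_, length(pvalues))
  ok <- !is.na(pvalues)
  q[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  q
}

#' Render an association scan as a report table
#'
#' Column layout of the candidate-gene report: gene, SNP (annotated
#' `minor>major`), group MAFs, adjusted p, OR with 95% CI, and — when an RDM
#' result is supplied — the percentage of significant sub-samples.
#'
#' @param scan result of [run_scan()].
#' @param geno the genotype matrix the scan was run on (for allele labels).
#' @param rdm optional result of [rdm_scan()].
#' @return data.frame with columns GENE, SNP, MAF_C, MAF_P, p, OR, CI, RDM.
#' @export
association_report <- function(scan, geno, rdm = NULL) {
  i <- match(scan$snp_id, geno$snps$snp_id)
  snp_lab <- paste0(scan$snp_id, geno$snps$allele_minor[i], ">",
                    geno$snps$allele_major[i])
  rdm_col <- rep(NA_character_, nrow(scan))
  if (!is.null(rdm)) {
    k <- match(scan$snp_id, rdm$unit)
    pct <- 100 * rdm$fraction_significant[k]
    rdm_col <- ifelse(is.na(pct), NA_character_,
                      ifelse(pct > 50, sprintf("%.0f", pct), "<50"))
  }
  data.frame(GENE = scan$gene, SNP = snp_lab,
             MAF_C = round(scan$maf_controls, 3),
             MAF_P = round(scan$maf_cases, 3),
             p = signif(scan$p_adj_model, 3),
             OR = sprintf("%.2f (%.2f-%.2f)", scan$or_adj,
                          scan$ci95_low, scan$ci95_high),
             RDM = rdm_col, stringsAsFactors = FALSE)
}
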