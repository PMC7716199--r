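#' Draw one case-control sub-sample
#'
#' Simple random sampling without replacement, independently within cases
#' and controls, under the session RNG.
#'
#' @param case_ids,control_ids sample id vectors.
#' @param n_cases_sub,n_controls_sub sub-sample sizes.
#' @return list with `cases` and `controls` id vectors.
#' @export
draw_subsample <- function(case_ids, control_ids, n_cases_sub,
                           n_controls_sub) {
  if (n_cases_sub > length(case_ids))
    stop("requested ", n_cases_sub, " cases from ", length(case_ids))
  if (n_controls_sub > length(control_ids))
    stop("requested ", n_controls_sub, " controls from ", length(control_ids))
  list(cases = sample(case_ids, n_cases_sub),
       controls = sample(control_ids, n_controls_sub))
}

#' Covariate balance check within a sub-sample
#'
#' Continuous variables (age) are compared between cases and controls with a
#' Welch t-test; ordinal variables (education, SES) with a Pearson
#' chi-square on the level-by-status table (no continuity correction). A
#' variable constant within the sub-sample cannot be tested and is treated
#' as balanced (p = 1) with a warning. The sub-sample is accepted iff every
#' requested variable has p >= `alpha`.
#'
#' @param subsample list with `cases`/`controls` ids (see [draw_subsample()]).
#' @param pheno `phenotype_table`.
#' @param variables subset of `c("age", "education", "ses")`.
#' @param alpha balance level.
#' @return list with `p` (named per-variable p-values) and `accept`.
#' @export
balance_check <- function(subsample, pheno, variables = c("age", "education", "ses"),
                          alpha = 0.05) {
  i_case <- match(subsample$cases, pheno$sample_id)
  i_ctrl <- match(subsample$controls, pheno$sample_id)
  if (anyNA(i_case) || anyNA(i_ctrl)) stop("subsample ids not in phenotype table")
  p <- vapply(variables, function(v) {
    x <- pheno[[v]][i_case]; z <- pheno[[v]][i_ctrl]
    if (length(unique(c(x, z))) < 2L) {
      warning("variable '", v, "' constant within subsample; treated as balanced")
      return(1)
    }
    if (v == "age") {
      stats::t.test(x, z)$p.value
    } else {
      tab <- table(factor(c(x, z)),
                   rep(c("case", "control"), c(length(x), length(z))))
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    }
  }, numeric(1))
  list(p = p, accept = all(p >= alpha))
}

#' Build the ensemble of balanced sub-samples
#'
#' Rejection sampling: sub-samples are drawn and kept only when they pass
#' [balance_check()] on every matching variable, until `n_subsamples`
#' accepted sub-samples exist. The attempt budget is 100x the requested
#' count; exhausting it means the cohort's confounding cannot be matched
#' away at these sizes and is a fatal diagnostic. With `redraw = FALSE` a
#' fixed number of `n_subsamples` draws is made instead and only the
#' passing ones kept (variable final count).
#'
#' @param pheno `phenotype_table`.
#' @param config a [run_config()]; uses `n_subsamples`, `n_cases_sub`,
#'   `n_controls_sub`, `balance_alpha`, `match_on`, `seed`.
#' @param redraw rejection-sample to a fixed accepted count (default) or not.
#' @return list of class `subsample_ensemble`: `subsamples`, `balance_p`
#'   (matrix), `n_attempted`, `n_accepted`, `acceptance_rate`, `match_on`.
#' @export
build_ensemble <- function(pheno, config = run_config(), redraw = TRUE) {
  if (!is.null(config$seed)) set.seed(config$seed)
  case_ids <- pheno$sample_id[pheno$status == "case"]
  ctrl_ids <- pheno$sample_id[pheno$status == "control"]
  target <- config$n_subsamples
  budget <- 100L * target
  subs <- vector("list", target)
  bal <- matrix(NA_real_, target, length(config$match_on),
                dimnames = list(NULL, config$match_on))
  acc <- 0L; att <- 0L
  while (acc < target) {
    if (att >= budget) {
      if (redraw)
        stop(sprintf(paste0("balance-matching budget exhausted: %d accepted ",
                            "of %d attempts (acceptance rate %.3f); the ",
                            "case/control covariate imbalance cannot be ",
                            "matched at these sub-sample sizes"),
                     acc, att, acc / att))
      break
    }
    s <- draw_subsample(case_ids, ctrl_ids, config$n_cases_sub,
                        config$n_controls_sub)
    att <- att + 1L
    if (!redraw && att > target) break
    b <- withCallingHandlers(
      balance_check(s, pheno, config$match_on, config$balance_alpha),
      warning = function(w) invokeRestart("muffleWarning"))
    if (b$accept) {
      acc <- acc + 1L
      subs[[acc]] <- s
      bal[acc, ] <- b$p
    }
  }
  structure(list(subsamples = subs[seq_len(acc)],
                 balance_p = bal[seq_len(acc), , drop = FALSE],
                 n_attempted = att, n_accepted = acc,
                 acceptance_rate = acc / att,
                 match_on = config$match_on, seed = config$seed),
            class = "subsample_ensemble")
}

#' @export
print.subsample_ensemble <- function(x, ...) {
  cat(sprintf(paste0("subsample_ensemble: %d accepted / %d attempted ",
                     "(rate %.2f), matched on %s\n"),
              x$n_accepted, x$n_attempted, x$acceptance_rate,
              paste(x$match_on, collapse = ", ")))
  invisible(x)
}

#' Randomized sub-sampling (RDM) scan over SNPs
#'
#' Within each accepted sub-sample the SNP-level QC (call rate, MAF) is
#' re-applied — a SNP failing it there is simply not evaluated in that
#' sub-sample — and the adjusted additive logistic model of [run_scan()] is
#' refit. A unit is kept when the fraction of sub-samples with p below
#' `test_alpha` strictly exceeds `keep_fraction`. Sub-sample fits that fail
#' or separate count as non-evaluated, never as significant.
#'
#' @param geno QC'd [genotype_matrix()].
#' @param pheno `phenotype_table`.
#' @param ensemble a `subsample_ensemble` built on the same phenotype table.
#' @param config a [run_config()].
#' @return data.frame, one row per SNP: `unit`, `n_evaluated`,
#'   `n_significant`, `fraction_significant`, `keep`, `or_median`,
#'   `or_ci_low`, `or_ci_high` (2.5/97.5 percentiles of per-sub-sample ORs).
#' @export
rdm_scan <- function(geno, pheno, ensemble, config = run_config()) {
  idx <- match(geno$samples, pheno$sample_id)
  ph <- pheno[idx, ]
  y_all <- as.integer(ph$status == "case")
  base_ok <- stats::complete.cases(ph[, c("age", "bmi", "anc_eur")])
  m <- ncol(geno$dosage)
  B <- length(ensemble$subsamples)
  pmat <- matrix(NA_real_, m, B)
  ormat <- matrix(NA_real_, m, B)
  row_of <- stats::setNames(seq_along(geno$samples), geno$samples)
  for (b in seq_len(B)) {
    s <- ensemble$subsamples[[b]]
    rows <- c(row_of[s$cases], row_of[s$controls])
    rows <- rows[!is.na(rows)]
    res <- subsample_fit(geno$dosage[rows, , drop = FALSE],
                         y_all[rows], ph[rows, ], base_ok[rows], config)
    pmat[, b] <- res$p
    ormat[, b] <- res$or
  }
  summarize_rdm(geno$snps$snp_id, pmat, ormat, config)
}

subsample_fit <- function(dos, y, ph, base_ok, config) {
  n <- nrow(dos); m <- ncol(dos)
  p <- rep(NA_real_, m); or <- rep(NA_real_, m)
  cr <- colMeans(!is.na(dos))
  Xbase <- adjust_design(ph)
  for (j in seq_len(m)) {
    if (cr[j] < config$snp_call_min) next
    d <- dos[, j]
    obs <- d[!is.na(d)]
    if (length(obs) == 0L) next
    f <- sum(obs) / (2 * length(obs))
    if (min(f, 1 - f) < config$maf_min) next
    use <- base_ok & !is.na(d)
    if (length(unique(y[use])) < 2L) next
    fit <- tryCatch(
      fit_logistic(y[use], cbind(Xbase[use, , drop = FALSE], dosage = d[use]),
                   check_rank = FALSE),
      error = function(e) NULL)
    if (is.null(fit) || fit$separated) next
    k <- length(fit$beta)
    p[j] <- fit$p[[k]]
    or[j] <- exp(fit$beta[[k]])
  }
  list(p = p, or = or)
}

summarize_rdm <- function(units, pmat, ormat, config) {
  n_eval <- rowSums(!is.na(pmat))
  n_sig <- rowSums(pmat < config$test_alpha, na.rm = TRUE)
  frac <- ifelse(n_eval > 0, n_sig / n_eval, NA_real_)
  or_med <- apply(ormat, 1L, stats::median, na.rm = TRUE)
  or_lo <- apply(ormat, 1L, stats::quantile, probs = 0.025, na.rm = TRUE,
                 names = FALSE)
  or_hi <- apply(ormat, 1L, stats::quantile, probs = 0.975, na.rm = TRUE,
                 names = FALSE)
  or_med[n_eval == 0] <- or_lo[n_eval == 0] <- or_hi[n_eval == 0] <- NA_real_
  data.frame(unit = units, n_evaluated = n_eval, n_significant = n_sig,
             fraction_significant = frac,
             keep = !is.na(frac) & frac > config$keep_fraction,
             or_median = or_med, or_ci_low = or_lo, or_ci_high = or_hi,
             stringsAsFactors = FALSE)
}
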