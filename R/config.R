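#' Analysis run configuration
#'
#' Assembles the thresholds and sizes used across the pipeline stages:
#' quality control, the randomized matched sub-sampling (RDM) procedure and
#' the haplotype analysis. Defaults follow the study design this pipeline
#' implements: a 1% MAF floor and 90% call-rate floors at QC, and an RDM
#' ensemble of 1000 sub-samples of 100 cases + 108 controls with balance and
#' test levels of 0.05 and a strict ">50% significant" retention rule.
#'
#' @param maf_min minimum pooled minor allele frequency for a SNP to survive QC.
#' @param snp_call_min minimum per-SNP genotyping call rate.
#' @param sample_call_min minimum per-sample genotyping call rate.
#' @param hwe_alpha nominal level used when reporting Hardy-Weinberg
#'   deviations (FDR-adjusted p below this is flagged; never an exclusion).
#' @param maf_on compute the QC MAF on `"pooled"` samples (default) or
#'   `"controls"` only.
#' @param n_subsamples number of accepted sub-samples in the RDM ensemble.
#' @param n_cases_sub,n_controls_sub cases/controls per sub-sample, drawn
#'   without replacement.
#' @param balance_alpha a sub-sample is discarded if any matching variable
#'   differs between cases and controls at this level.
#' @param test_alpha per-sub-sample significance level counted by the RDM rule.
#' @param keep_fraction a unit is kept when its fraction of significant
#'   sub-samples strictly exceeds this.
#' @param match_on covariates that must be balanced within each sub-sample;
#'   subset of `c("age", "education", "ses")`.
#' @param ld_alpha level for the BH-adjusted pairwise-LD screen that decides
#'   which genes get a haplotype analysis.
#' @param em_tol convergence tolerance (max absolute frequency change) for the
#'   haplotype EM.
#' @param em_max_iter EM iteration cap.
#' @param rare_hap_pool_freq haplotypes rarer than this (pooled frequency) are
#'   merged into a single "rare" class before association.
#' @param seed optional integer seed controlling every stochastic stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(maf_min = 0.01,
                       snp_call_min = 0.90,
                       sample_call_min = 0.90,
                       hwe_alpha = 0.05,
                       maf_on = c("pooled", "controls"),
                       n_subsamples = 1000L,
                       n_cases_sub = 100L,
                       n_controls_sub = 108L,
                       balance_alpha = 0.05,
                       test_alpha = 0.05,
                       keep_fraction = 0.5,
                       match_on = c("age", "education", "ses"),
                       ld_alpha = 0.05,
                       em_tol = 1e-8,
                       em_max_iter = 1000L,
                       rare_hap_pool_freq = 0.01,
                       seed = NULL) {
  maf_on <- match.arg(maf_on)
  cfg <- list(
    maf_min = maf_min, snp_call_min = snp_call_min,
    sample_call_min = sample_call_min, hwe_alpha = hwe_alpha,
    maf_on = maf_on,
    n_subsamples = as.integer(n_subsamples),
    n_cases_sub = as.integer(n_cases_sub),
    n_controls_sub = as.integer(n_controls_sub),
    balance_alpha = balance_alpha, test_alpha = test_alpha,
    keep_fraction = keep_fraction,
    match_on = match_on,
    ld_alpha = ld_alpha, em_tol = em_tol,
    em_max_iter = as.integer(em_max_iter),
    rare_hap_pool_freq = rare_hap_pool_freq,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  in01 <- c("maf_min", "snp_call_min", "sample_call_min", "hwe_alpha",
            "balance_alpha", "test_alpha", "keep_fraction", "ld_alpha",
            "rare_hap_pool_freq")
  for (nm in in01) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v >= 1)
      stop(sprintf("config field '%s' must be a single number in [0, 1)", nm))
  }
  pos <- c("n_subsamples", "n_cases_sub", "n_controls_sub", "em_max_iter")
  for (nm in pos) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1)
      stop(sprintf("config field '%s' must be a positive integer", nm))
  }
  if (!is.numeric(cfg$em_tol) || cfg$em_tol <= 0 || cfg$em_tol >= 1)
    stop("config field 'em_tol' must be in (0, 1)")
  bad <- setdiff(cfg$match_on, c("age", "education", "ses"))
  if (length(bad))
    stop("unknown matching variable(s): ", paste(bad, collapse = ", "))
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Flat keys named as the arguments of [run_config()]; keys absent from the
#' file keep their defaults, and arguments passed through `...` override the
#' file (the override order a command-line driver needs).
#'
#' @param path YAML file path.
#' @param ... overrides, as in [run_config()].
#' @return A `run_config` list.
#' @export
load_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("config file must contain a YAML mapping: ", path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  vals[names(list(...))] <- list(...)
  do.call(run_config, vals)
}
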