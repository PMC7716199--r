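#' Minor allele frequency from dosages
#'
#' Computes the coded-allele frequency `sum(d) / (2 * n_nonmissing)` and
#' folds it to the minor side: if the coded allele's frequency exceeds 0.5
#' the returned value is `1 - f` and the `"flipped"` attribute is `TRUE`.
#'
#' @param dosages integer vector in \{0, 1, 2, NA\}.
#' @return The minor allele frequency (numeric scalar) with attribute
#'   `flipped`.
#' @export
compute_maf <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (length(d) == 0L) stop("MAF undefined: all genotypes missing")
  f <- sum(d) / (2 * length(d))
  flipped <- f > 0.5
  structure(if (flipped) 1 - f else f, flipped = flipped)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the total sample size and minor allele
#' count, heterozygote counts of the same parity are enumerated, and the
#' p-value is the sum of the conditional probabilities of all tables no more
#' probable than the observed one (plain exact test, no mid-p). Probabilities
#' are computed directly from log-factorials.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative integers, any
#'   orientation; the test is symmetric in AA/aa).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1L) stop("empty genotype table")
  n1 <- 2L * min(n_AA, n_aa) + n_Aa       # minor allele count
  if (n1 == 0L) return(1.0)
  het <- seq.int(n1 %% 2L, min(n1, 2L * n - n1), by = 2L)
  # log P(nAa = h | n, n1) up to a constant
  logp <- lgamma(n + 1) -
    lgamma((n1 - het) / 2 + 1) - lgamma(het + 1) -
    lgamma(n - (n1 + het) / 2 + 1) + het * log(2)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, het)]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

#' Apply the QC filters and report Hardy-Weinberg screening
#'
#' Filter order is fixed and documented, since attrition depends on it:
#' (1) drop SNPs with call rate below `snp_call_min`; (2) drop samples with
#' call rate below `sample_call_min`, computed on the surviving SNPs;
#' (3) drop SNPs with MAF below `maf_min` on the surviving samples. The HWE
#' exact test is then computed per SNP in controls (and in cases) on the
#' final set and BH-adjusted; it is reported, never used for exclusion.
#'
#' @param geno a [genotype_matrix()].
#' @param pheno matching `phenotype_table` (used for the control-group HWE
#'   screen and, with `maf_on = "controls"`, the MAF filter).
#' @param config a [run_config()].
#' @return list with `geno` (filtered) and `report` (list with `snps`,
#'   `samples`, `hwe` data.frames and a `summary` of attrition counts).
#' @export
apply_filters <- function(geno, pheno, config = run_config()) {
  d0 <- geno$dosage
  cr_snp <- colMeans(!is.na(d0))
  keep_snp1 <- cr_snp >= config$snp_call_min

  d1 <- d0[, keep_snp1, drop = FALSE]
  cr_samp <- rowMeans(!is.na(d1))
  if (ncol(d1) == 0L) cr_samp <- rep(1, nrow(d0))
  keep_samp <- cr_samp >= config$sample_call_min

  d2 <- d1[keep_samp, , drop = FALSE]
  st <- pheno$status[match(geno$samples, pheno$sample_id)]
  maf_rows <- if (config$maf_on == "controls") {
    which(keep_samp & !is.na(st) & st == "control")
  } else which(keep_samp)
  d_maf <- d0[maf_rows, keep_snp1, drop = FALSE]
  maf2 <- apply(d_maf, 2L, function(x)
    if (all(is.na(x))) 0 else as.numeric(compute_maf(x)))
  keep_snp2 <- maf2 >= config$maf_min

  final_snps <- which(keep_snp1)[keep_snp2]
  final_samp <- which(keep_samp)
  out <- subset_genotypes(geno, samples = final_samp, snps = final_snps)

  # per-SNP report over the input set
  maf_all <- apply(d0, 2L, function(x)
    if (all(is.na(x))) NA_real_ else as.numeric(compute_maf(x)))
  snp_rep <- data.frame(
    snp_id = geno$snps$snp_id,
    call_rate = cr_snp,
    maf = maf_all,
    pass_call = keep_snp1,
    pass_maf = replace(rep(NA, ncol(d0)), which(keep_snp1), keep_snp2),
    kept = seq_len(ncol(d0)) %in% final_snps,
    stringsAsFactors = FALSE)
  samp_rep <- data.frame(
    sample_id = geno$samples,
    call_rate = cr_samp,
    kept = keep_samp, stringsAsFactors = FALSE)

  hwe <- hwe_screen(out, pheno, config)

  report <- list(
    snps = snp_rep, samples = samp_rep, hwe = hwe,
    summary = c(snps_in = ncol(d0), snps_out = ncol(out$dosage),
                samples_in = nrow(d0), samples_out = nrow(out$dosage),
                snps_fail_call = sum(!keep_snp1),
                samples_fail_call = sum(!keep_samp),
                snps_fail_maf = sum(!keep_snp2)))
  if (ncol(out$dosage) == 0L || nrow(out$dosage) == 0L)
    stop(sprintf(paste0("QC removed everything: %d/%d SNPs failed call rate, ",
                        "%d/%d samples failed call rate, %d SNPs failed MAF"),
                 sum(!keep_snp1), ncol(d0), sum(!keep_samp), nrow(d0),
                 sum(!keep_snp2)))
  list(geno = out, report = report)
}

hwe_screen <- function(geno, pheno, config) {
  st <- pheno$status[match(geno$samples, pheno$sample_id)]
  one_group <- function(rows) {
    vapply(seq_len(ncol(geno$dosage)), function(j) {
      d <- geno$dosage[rows, j]
      d <- d[!is.na(d)]
      if (length(d) == 0L) return(NA_real_)
      hwe_exact_test(sum(d == 2L), sum(d == 1L), sum(d == 0L))
    }, numeric(1))
  }
  p_ctrl <- one_group(which(!is.na(st) & st == "control"))
  p_case <- one_group(which(!is.na(st) & st == "case"))
  data.frame(
    snp_id = geno$snps$snp_id,
    hwe_p_controls = p_ctrl,
    hwe_q_controls = bh_fdr(p_ctrl),
    hwe_p_cases = p_case,
    hwe_q_cases = bh_fdr(p_case),
    hwe_flag = !is.na(p_ctrl) & bh_fdr(p_ctrl) < config$hwe_alpha,
    stringsAsFactors = FALSE)
}
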