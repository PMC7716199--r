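# Haplotype machinery: EM frequency estimation from unphased genotypes,
# pairwise LD, and haplotype association on expected dosages.
#
# Internally a haplotype is a string over {0,1} (1 = minor allele) ordered
# as the SNP set; display labels substitute the actual allele characters.

enumerate_pairs <- function(pattern) {
  # pattern: integer vector of dosages (0/1/2) at k SNPs, no NA.
  # Returns a 2-column character matrix of compatible (h1, h2) diplotypes;
  # the first heterozygous site is pinned to h1 so unordered pairs are unique.
  k <- length(pattern)
  base <- integer(k)
  base[pattern == 2L] <- 1L
  het <- which(pattern == 1L)
  if (length(het) == 0L) {
    h <- paste(base, collapse = "")
    return(matrix(c(h, h), 1L, 2L))
  }
  free <- het[-1L]
  n_free <- length(free)
  combos <- as.matrix(expand.grid(rep(list(0:1), n_free)))
  out <- matrix("", max(1L, nrow(combos)), 2L)
  for (r in seq_len(nrow(out))) {
    h1 <- base; h2 <- base
    h1[het[1L]] <- 1L; h2[het[1L]] <- 0L
    if (n_free) {
      h1[free] <- combos[r, ]
      h2[free] <- 1L - combos[r, ]
    }
    out[r, ] <- c(paste(h1, collapse = ""), paste(h2, collapse = ""))
  }
  out
}

em_core <- function(dos, tol = 1e-8, max_iter = 1000L) {
  # dos: complete n x k dosage matrix. Returns haplotype frequencies, the
  # log-likelihood trace, and per-pattern posterior pair weights.
  n <- nrow(dos)
  if (n == 0L) stop("no complete genotypes to estimate haplotypes from")
  key <- apply(dos, 1L, paste, collapse = "")
  tab <- table(key)
  pats <- names(tab)
  cnt <- as.numeric(tab)
  pair_list <- lapply(pats, function(k0)
    enumerate_pairs(as.integer(strsplit(k0, "")[[1L]])))
  haps <- sort(unique(unlist(pair_list)))
  H <- length(haps)
  h1 <- match(unlist(lapply(pair_list, `[`, , 1L)), haps)
  h2 <- match(unlist(lapply(pair_list, `[`, , 2L)), haps)
  pat_id <- rep(seq_along(pats), vapply(pair_list, nrow, integer(1)))
  mult <- ifelse(h1 == h2, 1, 2)

  f <- rep(1 / H, H)
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    wp <- f[h1] * f[h2] * mult
    denom <- as.vector(rowsum(wp, pat_id))
    ll_trace <- c(ll_trace, sum(cnt * log(denom)))
    post <- wp / denom[pat_id] * cnt[pat_id]
    counts <- numeric(H)
    a1 <- rowsum(post, h1); counts[as.integer(rownames(a1))] <- a1
    a2 <- rowsum(post, h2)
    counts[as.integer(rownames(a2))] <- counts[as.integer(rownames(a2))] + a2
    f_new <- counts / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
  }
  wp <- f[h1] * f[h2] * mult
  denom <- as.vector(rowsum(wp, pat_id))
  post <- wp / pmax(denom[pat_id], .Machine$double.xmin)
  # expected per-pattern haplotype dosage (rows: pattern, cols: haplotype)
  dose_pat <- matrix(0, length(pats), H)
  for (r in seq_along(pat_id)) {
    i <- pat_id[r]
    dose_pat[i, h1[r]] <- dose_pat[i, h1[r]] + post[r]
    dose_pat[i, h2[r]] <- dose_pat[i, h2[r]] + post[r]
  }
  list(haps = haps, freq = stats::setNames(f, haps),
       loglik = ll_trace, iterations = it, converged = converged,
       pattern = pats, dose_pat = dose_pat, row_pattern = match(key, pats))
}

#' EM haplotype frequencies and expected dosages over a SNP set
#'
#' Standard multilocus EM under haplotype-level Hardy-Weinberg: the E-step
#' weights each individual's compatible diplotypes proportionally to
#' `f_h1 * f_h2` (times 2 when heterozygous), the M-step re-estimates
#' frequencies from expected counts; initialization is uniform over
#' haplotypes compatible with the observed genotypes. Individuals missing
#' any of the k genotypes are excluded from estimation (their dosages are
#' `NA`). Frequencies are estimated separately in cases and controls for
#' reporting, and pooled — phenotype-blind — for the per-individual expected
#' haplotype dosages used in association.
#'
#' @param geno a [genotype_matrix()].
#' @param snp_ids the SNPs of the haplotype set, in order (2 to 6 of them).
#' @param pheno optional `phenotype_table` for the per-group frequencies.
#' @param config a [run_config()] (`em_tol`, `em_max_iter`).
#' @return list of class `haplotype_set`: `snp_ids`, `haplotypes` (binary
#'   strings), `labels` (allele characters), `freq_pooled`, `freq_cases`,
#'   `freq_controls`, `dosage` (n x H expected minor-haplotype dosages, rows
#'   aligned to `geno$samples`), `loglik`, `n_em_iterations`, `converged`,
#'   `n_used`.
#' @export
em_haplotypes <- function(geno, snp_ids, pheno = NULL, config = run_config()) {
  k <- length(snp_ids)
  if (k < 2L || k > 6L) stop("haplotype sets must span 2-6 SNPs")
  j <- match(snp_ids, geno$snps$snp_id)
  if (anyNA(j)) stop("unknown snp id(s): ",
                     paste(snp_ids[is.na(j)], collapse = ", "))
  dos <- geno$dosage[, j, drop = FALSE]
  complete <- stats::complete.cases(dos)
  if (!any(complete)) stop("no individual has complete genotypes over the set")
  pooled <- em_core(dos[complete, , drop = FALSE],
                    config$em_tol, config$em_max_iter)
  H <- length(pooled$haps)
  dosage <- matrix(NA_real_, nrow(dos), H,
                   dimnames = list(geno$samples, pooled$haps))
  dosage[complete, ] <- pooled$dose_pat[pooled$row_pattern, , drop = FALSE]

  freq_c <- freq_t <- stats::setNames(rep(NA_real_, H), pooled$haps)
  if (!is.null(pheno)) {
    st <- pheno$status[match(geno$samples, pheno$sample_id)]
    for (g in c("case", "control")) {
      rows <- complete & !is.na(st) & st == g
      if (sum(rows) == 0L) next
      em_g <- em_core(dos[rows, , drop = FALSE],
                      config$em_tol, config$em_max_iter)
      fg <- stats::setNames(rep(0, H), pooled$haps)
      shared <- intersect(em_g$haps, pooled$haps)
      fg[shared] <- em_g$freq[shared]
      if (g == "case") freq_c <- fg else freq_t <- fg
    }
  }
  lab <- vapply(pooled$haps, function(h) {
    bits <- strsplit(h, "")[[1L]]
    paste(ifelse(bits == "1", geno$snps$allele_minor[j],
                 geno$snps$allele_major[j]), collapse = "")
  }, character(1))
  structure(list(snp_ids = snp_ids, haplotypes = pooled$haps, labels = lab,
                 freq_pooled = pooled$freq, freq_cases = freq_c,
                 freq_controls = freq_t, dosage = dosage,
                 loglik = pooled$loglik, n_em_iterations = pooled$iterations,
                 converged = pooled$converged, n_used = sum(complete)),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set over %s: %d haplotypes, %d individuals, %d EM iterations\n",
              paste(x$snp_ids, collapse = "|"), length(x$haplotypes),
              x$n_used, x$n_em_iterations))
  invisible(x)
}

#' Pairwise linkage disequilibrium from unphased dosages
#'
#' Two-SNP haplotype frequencies by EM, then `D = p11 - pA pB`,
#' `D' = |D| / Dmax`, `r2 = D^2 / (pA qA pB qB)` and a chi-square p-value
#' from `chi2 = 2 n r2` (1 df), n = individuals with both genotypes.
#'
#' @param dosA,dosB dosage vectors of the two SNPs.
#' @param config a [run_config()].
#' @return list with `D`, `Dprime`, `r2`, `chi2`, `p`, `n`.
#' @export
ld_pair <- function(dosA, dosB, config = run_config()) {
  ok <- !is.na(dosA) & !is.na(dosB)
  dA <- dosA[ok]; dB <- dosB[ok]
  n <- length(dA)
  if (n == 0L) stop("no shared non-missing genotypes")
  if (length(unique(dA)) < 2L || length(unique(dB)) < 2L)
    stop("LD undefined: a SNP is monomorphic on the shared samples")
  em <- em_core(cbind(dA, dB), config$em_tol, config$em_max_iter)
  p11 <- if ("11" %in% em$haps) unname(em$freq["11"]) else 0
  pA <- sum(dA) / (2 * n); pB <- sum(dB) / (2 * n)
  D <- p11 - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (dmax == 0) 0 else abs(D) / dmax
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  chi2 <- 2 * n * r2
  list(D = D, Dprime = min(dprime, 1), r2 = min(r2, 1), chi2 = chi2,
       p = stats::pchisq(chi2, 1L, lower.tail = FALSE), n = n)
}

#' All-pairs LD within a SNP set
#'
#' @param geno a [genotype_matrix()].
#' @param snp_ids SNPs to cross (default: all).
#' @param config a [run_config()].
#' @return data.frame of SNP pairs with `D`, `Dprime`, `r2`, `p` (failed
#'   pairs carry `NA` and a note).
#' @export
ld_matrix <- function(geno, snp_ids = geno$snps$snp_id, config = run_config()) {
  j <- match(snp_ids, geno$snps$snp_id)
  pairs <- utils::combn(seq_along(j), 2L)
  out <- lapply(seq_len(ncol(pairs)), function(q) {
    a <- pairs[1L, q]; b <- pairs[2L, q]
    row <- data.frame(snp_a = snp_ids[a], snp_b = snp_ids[b],
                      D = NA_real_, Dprime = NA_real_, r2 = NA_real_,
                      p = NA_real_, note = "", stringsAsFactors = FALSE)
    tryCatch({
      ld <- ld_pair(geno$dosage[, j[a]], geno$dosage[, j[b]], config)
      row$D <- ld$D; row$Dprime <- ld$Dprime; row$r2 <- ld$r2; row$p <- ld$p
      row
    }, error = function(e) { row$note <- conditionMessage(e); row })
  })
  do.call(rbind, out)
}

#' Gene-level LD screen for haplotype analysis
#'
#' For each gene with two or more SNPs, pairwise LD p-values are BH-adjusted
#' within the gene; the gene enters the haplotype analysis with the SNPs
#' that belong to at least one significant pair (q < `ld_alpha`), provided
#' there are two or more of them.
#'
#' @param geno a [genotype_matrix()] whose `snps` table has a `gene` column.
#' @param config a [run_config()].
#' @return named list: gene -> character vector of snp_ids (position order).
#' @export
ld_gene_screen <- function(geno, config = run_config()) {
  if (!"gene" %in% names(geno$snps))
    stop("ld_gene_screen needs a 'gene' column in the SNP table")
  out <- list()
  for (g in unique(geno$snps$gene)) {
    ids <- geno$snps$snp_id[geno$snps$gene == g]
    if (length(ids) < 2L) next
    ld <- ld_matrix(geno, ids, config)
    ld$q <- bh_fdr(ld$p)
    sig <- ld[!is.na(ld$q) & ld$q < config$ld_alpha, , drop = FALSE]
    keep <- unique(c(sig$snp_a, sig$snp_b))
    if (length(keep) >= 2L) {
      ord <- order(match(keep, geno$snps$snp_id))
      out[[g]] <- keep[ord]
    }
  }
  out
}

#' Haplotype association on expected dosages
#'
#' One-vs-rest covariate-adjusted logistic regression per haplotype, with
#' the expected (posterior-mean) haplotype dosage from the pooled EM as the
#' predictor and the SNP-scan covariates (age, BMI, European ancestry).
#' Haplotypes rarer than `rare_hap_pool_freq` (pooled) are merged into a
#' single `"rare"` class. BH FDR across the set's haplotypes.
#'
#' @param hapset a [em_haplotypes()] result (built with `pheno`).
#' @param pheno `phenotype_table`.
#' @param config a [run_config()].
#' @return data.frame per haplotype: `haplotype`, `label`, `freq_cases`,
#'   `freq_controls`, `freq_pooled`, `beta`, `se`, `or`, `ci95_low`,
#'   `ci95_high`, `p`, `q_fdr`, `n_used`, `note`.
#' @export
haplotype_association <- function(hapset, pheno, config = run_config()) {
  rare <- hapset$freq_pooled < config$rare_hap_pool_freq
  if (all(rare)) stop("every haplotype is below the rare-pooling threshold")
  dos <- hapset$dosage[, !rare, drop = FALSE]
  labs <- hapset$labels[!rare]
  haps <- hapset$haplotypes[!rare]
  fp <- hapset$freq_pooled[!rare]
  fc <- hapset$freq_cases[!rare]
  ft <- hapset$freq_controls[!rare]
  if (any(rare)) {
    dos <- cbind(dos, rare = rowSums(
      hapset$dosage[, rare, drop = FALSE]))
    labs <- c(labs, "rare"); haps <- c(haps, "rare")
    fp <- c(fp, rare = sum(hapset$freq_pooled[rare]))
    fc <- c(fc, rare = sum(hapset$freq_cases[rare]))
    ft <- c(ft, rare = sum(hapset$freq_controls[rare]))
  }
  idx <- match(rownames(hapset$dosage), pheno$sample_id)
  ph <- pheno[idx, ]
  y <- as.integer(ph$status == "case")
  base_ok <- stats::complete.cases(ph[, c("age", "bmi", "anc_eur")])
  out <- lapply(seq_along(haps), function(h) {
    row <- data.frame(haplotype = haps[h], label = labs[h],
                      freq_cases = unname(fc[h]), freq_controls = unname(ft[h]),
                      freq_pooled = unname(fp[h]),
                      beta = NA_real_, se = NA_real_, or = NA_real_,
                      ci95_low = NA_real_, ci95_high = NA_real_, p = NA_real_,
                      n_used = 0L, note = "", stringsAsFactors = FALSE)
    tryCatch({
      d <- dos[, h]
      use <- base_ok & !is.na(d)
      fit <- fit_logistic(y[use], cbind(adjust_design(ph, which(use)),
                                        hap = d[use]))
      k <- length(fit$beta)
      row$beta <- fit$beta[[k]]; row$se <- fit$se[[k]]
      row$or <- exp(row$beta)
      row$ci95_low <- exp(row$beta - 1.96 * row$se)
      row$ci95_high <- exp(row$beta + 1.96 * row$se)
      row$p <- fit$p[[k]]
      row$n_used <- sum(use)
      if (fit$separated) row$note <- "separation"
      row
    }, error = function(e) { row$note <- conditionMessage(e); row })
  })
  res <- do.call(rbind, out)
  res$q_fdr <- bh_fdr(res$p)
  res
}

#' RDM scan over the haplotypes of a SNP set
#'
#' The EM is re-run inside every accepted sub-sample (phenotype-blind,
#' pooled) and each haplotype — matched across sub-samples by allele string
#' — is tested with the adjusted one-vs-rest logistic model. Aggregation is
#' identical to the SNP RDM: a haplotype absent (or rarer than the pooling
#' threshold) in a sub-sample is not evaluated there.
#'
#' @param geno QC'd [genotype_matrix()].
#' @param snp_ids haplotype-set SNPs.
#' @param pheno `phenotype_table`.
#' @param ensemble a `subsample_ensemble`.
#' @param config a [run_config()].
#' @return data.frame as [rdm_scan()], one row per full-sample haplotype.
#' @export
haplotype_rdm <- function(geno, snp_ids, pheno, ensemble,
                          config = run_config()) {
  full <- em_haplotypes(geno, snp_ids, pheno, config)
  haps <- full$haplotypes
  H <- length(haps)
  j <- match(snp_ids, geno$snps$snp_id)
  idx <- match(geno$samples, pheno$sample_id)
  ph <- pheno[idx, ]
  y_all <- as.integer(ph$status == "case")
  base_ok <- stats::complete.cases(ph[, c("age", "bmi", "anc_eur")])
  row_of <- stats::setNames(seq_along(geno$samples), geno$samples)
  B <- length(ensemble$subsamples)
  pmat <- matrix(NA_real_, H, B)
  ormat <- matrix(NA_real_, H, B)
  for (b in seq_len(B)) {
    s <- ensemble$subsamples[[b]]
    rows <- c(row_of[s$cases], row_of[s$controls])
    rows <- rows[!is.na(rows)]
    dos <- geno$dosage[rows, j, drop = FALSE]
    complete <- stats::complete.cases(dos)
    if (sum(complete) < 10L) next
    em <- tryCatch(em_core(dos[complete, , drop = FALSE],
                           config$em_tol, config$em_max_iter),
                   error = function(e) NULL)
    if (is.null(em)) next
    dosage <- em$dose_pat[em$row_pattern, , drop = FALSE]
    yb <- y_all[rows][complete]
    phb <- ph[rows, ][complete, ]
    okb <- base_ok[rows][complete]
    Xb <- adjust_design(phb)
    for (h in seq_len(H)) {
      hi <- match(haps[h], em$haps)
      if (is.na(hi) || em$freq[hi] < config$rare_hap_pool_freq) next
      d <- dosage[, hi]
      use <- okb
      if (length(unique(yb[use])) < 2L) next
      fit <- tryCatch(
        fit_logistic(yb[use], cbind(Xb[use, , drop = FALSE], hap = d[use]),
                     check_rank = FALSE),
        error = function(e) NULL)
      if (is.null(fit) || fit$separated) next
      k <- length(fit$beta)
      pmat[h, b] <- fit$p[[k]]
      ormat[h, b] <- exp(fit$beta[[k]])
    }
  }
  summarize_rdm(haps, pmat, ormat, config)
}

#' Render a haplotype analysis as a report table
#'
#' @param assoc result of [haplotype_association()].
#' @param gene gene name for the GENE column.
#' @param rdm optional result of [haplotype_rdm()] (matched by binary string).
#' @return data.frame with columns GENE, HAPLOTYPE, FP, FC, p, OR, RDM.
#' @export
haplotype_report <- function(assoc, gene = NA_character_, rdm = NULL) {
  rdm_col <- rep(NA_character_, nrow(assoc))
  if (!is.null(rdm)) {
    k <- match(assoc$haplotype, rdm$unit)
    pct <- 100 * rdm$fraction_significant[k]
    rdm_col <- ifelse(is.na(pct), NA_character_,
                      ifelse(pct > 50, sprintf("%.0f", pct), "<50"))
  }
  data.frame(GENE = gene, HAPLOTYPE = assoc$label,
             FP = round(assoc$freq_cases, 3),
             FC = round(assoc$freq_controls, 3),
             p = signif(assoc$p, 3),
             OR = round(assoc$or, 2),
             RDM = rdm_col, stringsAsFactors = FALSE)
}
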