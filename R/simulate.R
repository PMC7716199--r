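#' Simulation configuration for the admixed case-control generator
#'
#' Defaults emulate the cohort the pipeline targets: a three-way admixed
#' population (European/African/Native American) with predominantly European
#' ancestry, candidate-gene SNPs at intermediate frequencies, small LD blocks
#' of 2-4 SNPs, ancestry-correlated socioeconomic confounders that are also
#' associated with case status (the imbalance the RDM procedure neutralizes),
#' modest per-entry missingness, and pre-QC sample sizes of 176 cases and
#' 183 controls.
#'
#' @param n_cases,n_controls target case/control counts (drawn retrospectively
#'   from a population stream).
#' @param n_snps number of independent (non-block) SNPs.
#' @param dirichlet_alpha length-3 concentration for per-individual
#'   (EUR, AFR, NAT) ancestry proportions. The default `c(16, 2, 2)` gives a
#'   mean European proportion of 0.8 with most mass between 0.6 and 0.95.
#' @param fst Balding-Nichols divergence of each parental population from the
#'   ancestral frequency.
#' @param base_maf_range interval for ancestral minor-allele frequencies.
#' @param ld_blocks list of blocks, each `list(snps = k, hap_freq = f)` with
#'   `f` a named vector of ancestral haplotype frequencies over allele strings
#'   of length `k` in \{0 = major, 1 = minor\} (e.g. `c("00" = .5, "11" = .5)`).
#' @param effects data.frame with columns `unit` (`"snp"` or `"haplotype"`),
#'   `id` (a SNP id like `"snp007"`, or `"block<i>:<allelestring>"`) and
#'   `log_or` (additive per-copy log odds ratio).
#' @param confounder_model list: `ses_load`, `edu_load` (loadings of the
#'   European proportion on the latent Gaussians thresholded into 3-level SES
#'   and education), `bmi_anc_beta` (kg/m2 shift per unit European
#'   proportion), `bmi_sd`, `age_mean`, `age_sd`, `age_min` (years; ages are
#'   truncated below at `age_min`).
#' @param confounder_status_bias named log-ORs of `ses` (per level),
#'   `education` (per level) and `age` (per year, centered at 60) on case
#'   status. Nonzero values create the case/control covariate imbalance the
#'   RDM matching is designed to remove.
#' @param base_rate population case rate the status-model intercept is
#'   calibrated to before case enrichment.
#' @param missing_rate_snp,missing_rate_sample independent per-entry missing
#'   probabilities contributed by the SNP and the sample.
#' @param seed master seed; each stage (frequencies, gametes, covariates,
#'   missingness) uses its own stream derived from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 176L,
                       n_controls = 183L,
                       n_snps = 120L,
                       dirichlet_alpha = c(16, 2, 2),
                       fst = 0.1,
                       base_maf_range = c(0.05, 0.5),
                       ld_blocks = default_ld_blocks(),
                       effects = default_effects(),
                       confounder_model = list(
                         ses_load = 1.5, edu_load = 1.0,
                         bmi_anc_beta = -2, bmi_sd = 4,
                         age_mean = 60, age_sd = 8, age_min = 45),
                       confounder_status_bias = c(ses = 0.2,
                                                  education = -0.15,
                                                  age = 0.02),
                       base_rate = 0.10,
                       missing_rate_snp = 0.01,
                       missing_rate_sample = 0.005,
                       seed = NULL) {
  stopifnot(length(dirichlet_alpha) == 3L, all(dirichlet_alpha > 0),
            fst > 0, fst < 1,
            length(base_maf_range) == 2L,
            base_maf_range[1] > 0.01 - 1e-12, base_maf_range[2] <= 0.5,
            missing_rate_snp >= 0, missing_rate_snp < 1,
            missing_rate_sample >= 0, missing_rate_sample < 1,
            base_rate > 0, base_rate < 1)
  for (b in ld_blocks) {
    if (abs(sum(b$hap_freq) - 1) > 1e-9)
      stop("ld_block haplotype frequencies must sum to 1")
    if (any(nchar(names(b$hap_freq)) != b$snps))
      stop("ld_block haplotype labels must have length `snps`")
  }
  cfg <- list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              n_snps = as.integer(n_snps),
              dirichlet_alpha = dirichlet_alpha, fst = fst,
              base_maf_range = base_maf_range, ld_blocks = ld_blocks,
              effects = effects, confounder_model = confounder_model,
              confounder_status_bias = confounder_status_bias,
              base_rate = base_rate,
              missing_rate_snp = missing_rate_snp,
              missing_rate_sample = missing_rate_sample,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Default LD-block layout: three small blocks
#'
#' Two 2-SNP blocks and one 3-SNP block with common haplotypes, giving the
#' haplotype analysis something to estimate at study scale.
#' @return list of block definitions for [sim_config()].
#' @export
default_ld_blocks <- function() {
  list(
    list(snps = 2L, hap_freq = c("00" = 0.45, "01" = 0.10,
                                 "10" = 0.15, "11" = 0.30)),
    list(snps = 2L, hap_freq = c("00" = 0.55, "01" = 0.05,
                                 "10" = 0.10, "11" = 0.30)),
    list(snps = 3L, hap_freq = c("000" = 0.40, "100" = 0.20,
                                 "110" = 0.25, "111" = 0.15))
  )
}

#' Default planted effects
#'
#' A moderate risk SNP (OR 1.5), a stronger risk SNP (OR 1.9), a protective
#' SNP (OR 0.5) and a risk haplotype (OR 1.75) on the first block —
#' magnitudes in the range candidate-gene studies of this size report.
#' @return data.frame understood by [sim_config()].
#' @export
default_effects <- function() {
  data.frame(
    unit = c("snp", "snp", "snp", "haplotype"),
    id = c("snp001", "snp002", "snp003", "block1:11"),
    log_or = c(log(1.5), log(1.9), log(0.5), log(1.75)),
    stringsAsFactors = FALSE
  )
}

stage_seed <- function(seed, stage) {
  offs <- c(freqs = 101L, gametes = 211L, covariates = 307L,
            status = 401L, missingness = 503L, stream = 601L)
  (as.integer(seed) + 7919L * offs[[stage]]) %% 2147483597L
}

#' Balding-Nichols per-population allele frequencies
#'
#' For each SNP an ancestral frequency p is drawn uniformly from
#' `base_maf_range`; each parental population then draws its frequency from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F = fst`, so the across-population
#' mean is p and the variance is `F p (1-p)`. Frequencies are clipped to
#' `[0.01, 0.99]`.
#'
#' @param n_snps number of SNPs.
#' @param fst divergence parameter in (0, 1).
#' @param base_maf_range length-2 interval for the ancestral frequency.
#' @param n_pops number of parental populations.
#' @return list with `base` (length `n_snps`) and `pops`
#'   (`n_snps x n_pops` matrix).
#' @export
sample_ancestral_freqs <- function(n_snps, fst, base_maf_range = c(0.05, 0.5),
                                   n_pops = 3L) {
  stopifnot(fst > 0, fst < 1)
  p <- stats::runif(n_snps, base_maf_range[1], base_maf_range[2])
  k <- (1 - fst) / fst
  pops <- matrix(stats::rbeta(n_snps * n_pops, rep(p * k, n_pops),
                              rep((1 - p) * k, n_pops)),
                 n_snps, n_pops)
  pops <- pmin(pmax(pops, 0.01), 0.99)
  list(base = p, pops = pops)
}

#' Per-individual ancestry proportions
#'
#' @param n number of individuals.
#' @param alpha Dirichlet concentration, one entry per parental population.
#' @return `n x length(alpha)` matrix with rows summing to 1.
#' @export
sample_ancestry <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              n, length(alpha))
  g / rowSums(g)
}

block_pop_hap_freqs <- function(ld_blocks, fst, n_pops = 3L) {
  k <- (1 - fst) / fst
  lapply(ld_blocks, function(b) {
    f <- b$hap_freq
    pops <- vapply(seq_len(n_pops), function(j) {
      g <- stats::rgamma(length(f), shape = k * f)
      g / sum(g)
    }, numeric(length(f)))
    rownames(pops) <- names(f)
    pops                                    # n_hap x n_pops
  })
}

#' Simulate unphased genotypes given ancestry and population frequencies
#'
#' Independent SNPs: each of the two gametes carries the minor allele with
#' probability `sum_k anc_k * freq_k`. LD-block SNPs: each gamete draws a
#' whole block haplotype from the ancestry-mixed block haplotype frequencies.
#' Dosage is the sum over the two gametes.
#'
#' @param ancestry `n x K` ancestry proportion matrix (rows sum to 1).
#' @param pop_freqs `m x K` per-population minor-allele frequencies for the
#'   independent SNPs.
#' @param block_freqs optional list of `n_hap x K` per-population haplotype
#'   frequency matrices (rownames are allele strings), one per LD block;
#'   block SNPs are appended after the independent SNPs.
#' @return list with `dosage` (`n x m_total` integer matrix),
#'   `block_haplotypes` (per block, an `n x 2` character matrix of gamete
#'   allele strings) and `block_cols` (column indices of each block).
#' @export
simulate_genotypes <- function(ancestry, pop_freqs, block_freqs = NULL) {
  if (any(abs(rowSums(ancestry) - 1) > 1e-9))
    stop("ancestry rows must sum to 1")
  n <- nrow(ancestry)
  m <- if (is.null(pop_freqs)) 0L else nrow(pop_freqs)
  dos <- NULL
  if (m > 0L) {
    q <- ancestry %*% t(pop_freqs)              # n x m per-gamete minor prob
    g1 <- matrix(stats::runif(n * m) < q, n, m)
    g2 <- matrix(stats::runif(n * m) < q, n, m)
    dos <- matrix(as.integer(g1) + as.integer(g2), n, m)
  }
  block_haps <- list(); block_cols <- list()
  col_at <- m
  for (bi in seq_along(block_freqs)) {
    H <- block_freqs[[bi]]                      # n_hap x K
    labs <- rownames(H)
    k <- nchar(labs[1L])
    probs <- ancestry %*% t(H)                  # n x n_hap
    cum <- t(apply(probs, 1L, cumsum))
    draw <- function() {
      u <- stats::runif(n) * cum[, ncol(cum)]
      idx <- rowSums(cum < u) + 1L
      labs[idx]
    }
    h1 <- draw(); h2 <- draw()
    am <- matrix(as.integer(unlist(strsplit(h1, ""))), n, k, byrow = TRUE) +
          matrix(as.integer(unlist(strsplit(h2, ""))), n, k, byrow = TRUE)
    dos <- if (is.null(dos)) am else cbind(dos, am)
    block_haps[[bi]] <- cbind(h1, h2)
    block_cols[[bi]] <- col_at + seq_len(k)
    col_at <- col_at + k
  }
  list(dosage = dos, block_haplotypes = block_haps, block_cols = block_cols)
}

latent_cutpoints <- function(load, alpha) {
  # 3 roughly equal levels of a latent N(load*anc_eur, 1) at the population
  # ancestry distribution (normal approximation to the Dirichlet marginal)
  a0 <- sum(alpha)
  mu <- alpha[1] / a0
  v <- alpha[1] * (a0 - alpha[1]) / (a0^2 * (a0 + 1))
  m <- load * mu; s <- sqrt(load^2 * v + 1)
  stats::qnorm(c(1 / 3, 2 / 3), mean = m, sd = s)
}

draw_covariates <- function(ancestry, cm, alpha) {
  n <- nrow(ancestry)
  eur <- ancestry[, 1L]
  cut_ses <- latent_cutpoints(cm$ses_load, alpha)
  cut_edu <- latent_cutpoints(cm$edu_load, alpha)
  ses <- findInterval(cm$ses_load * eur + stats::rnorm(n), cut_ses) + 1L
  education <- findInterval(cm$edu_load * eur + stats::rnorm(n), cut_edu) + 1L
  age <- cm$age_mean + cm$age_sd * stats::qnorm(
    stats::runif(n,
                 stats::pnorm((cm$age_min - cm$age_mean) / cm$age_sd), 1))
  bmi <- 26 + cm$bmi_anc_beta * eur + stats::rnorm(n, sd = cm$bmi_sd)
  data.frame(age = age, bmi = bmi, ses = ses, education = education)
}

genetic_score <- function(sim, cfg, snp_ids) {
  n <- nrow(sim$dosage)
  sc <- numeric(n)
  eff <- cfg$effects
  if (is.null(eff) || nrow(eff) == 0L) return(sc)
  for (i in seq_len(nrow(eff))) {
    if (eff$unit[i] == "snp") {
      j <- match(eff$id[i], snp_ids)
      if (is.na(j)) stop("effect refers to unknown SNP: ", eff$id[i])
      sc <- sc + eff$log_or[i] * sim$dosage[, j]
    } else {
      parts <- strsplit(eff$id[i], ":", fixed = TRUE)[[1L]]
      bi <- as.integer(sub("block", "", parts[1L]))
      if (is.na(bi) || bi > length(sim$block_haplotypes))
        stop("effect refers to unknown block: ", eff$id[i])
      hd <- rowSums(sim$block_haplotypes[[bi]] == parts[2L])
      sc <- sc + eff$log_or[i] * hd
    }
  }
  sc
}

status_linpred <- function(score, cov, bias) {
  score +
    bias[["ses"]] * (cov$ses - 2) +
    bias[["education"]] * (cov$education - 2) +
    bias[["age"]] * (cov$age - 60)
}

#' Simulate a complete case-control dataset
#'
#' Draws a population stream (ancestry -> genotypes -> covariates -> case
#' status) and retains individuals by rejection until the requested case and
#' control counts are reached (retrospective sampling, so planted log-ORs are
#' the estimand of the logistic analysis). The status-model intercept is
#' calibrated numerically so the population case rate is `base_rate` before
#' enrichment. Missingness is injected last. Each stage draws from its own
#' RNG stream derived from `config$seed`, so e.g. changing the missingness
#' rate leaves the genotypes unchanged.
#'
#' @param config a [sim_config()].
#' @return list with `geno` (a [genotype_matrix()]), `pheno`
#'   (a `phenotype_table`) and `truth` (ancestry, population frequencies,
#'   planted effects, true block haplotypes, the calibrated intercept).
#' @export
simulate_dataset <- function(config) {
  cfg <- config
  if (!is.null(cfg$seed)) set.seed(stage_seed(cfg$seed, "freqs"))
  fr <- sample_ancestral_freqs(cfg$n_snps, cfg$fst, cfg$base_maf_range)
  bfr <- block_pop_hap_freqs(cfg$ld_blocks, cfg$fst)

  n_block_snps <- sum(vapply(cfg$ld_blocks, function(b) b$snps, integer(1)))
  m_tot <- cfg$n_snps + n_block_snps
  snp_ids <- sprintf("snp%03d", seq_len(m_tot))
  genes <- c(sprintf("gene%03d", seq_len(cfg$n_snps)),
             unlist(lapply(seq_along(cfg$ld_blocks), function(bi)
               rep(sprintf("blockgene%02d", bi), cfg$ld_blocks[[bi]]$snps))))

  need <- cfg$n_cases + cfg$n_controls
  if (!is.null(cfg$seed)) set.seed(stage_seed(cfg$seed, "stream"))

  # calibrate the intercept on a dedicated population batch
  calib <- draw_population(5000L, cfg, fr, bfr, snp_ids)
  lp <- status_linpred(calib$score, calib$cov, cfg$confounder_status_bias)
  intercept <- stats::uniroot(
    function(c0) mean(stats::plogis(c0 + lp)) - cfg$base_rate,
    c(-30, 10), tol = 1e-10)$root

  kept_case <- list(); kept_ctrl <- list()
  n_case <- 0L; n_ctrl <- 0L; drawn <- 0L
  batch <- max(2000L, 2L * need)
  while (n_case < cfg$n_cases || n_ctrl < cfg$n_controls) {
    if (drawn >= 100L * need)
      stop(sprintf(paste0("could not reach %d cases / %d controls within ",
                          "%d population draws (got %d / %d); ",
                          "check base_rate and effect sizes"),
                   cfg$n_cases, cfg$n_controls, 100L * need, n_case, n_ctrl))
    pop <- draw_population(batch, cfg, fr, bfr, snp_ids)
    drawn <- drawn + batch
    lp <- intercept + status_linpred(pop$score, pop$cov,
                                     cfg$confounder_status_bias)
    is_case <- stats::runif(batch) < stats::plogis(lp)
    take_case <- which(is_case)[seq_len(min(sum(is_case),
                                            cfg$n_cases - n_case))]
    take_ctrl <- which(!is_case)[seq_len(min(sum(!is_case),
                                             cfg$n_controls - n_ctrl))]
    if (length(take_case)) {
      kept_case[[length(kept_case) + 1L]] <- slice_population(pop, take_case)
      n_case <- n_case + length(take_case)
    }
    if (length(take_ctrl)) {
      kept_ctrl[[length(kept_ctrl) + 1L]] <- slice_population(pop, take_ctrl)
      n_ctrl <- n_ctrl + length(take_ctrl)
    }
  }
  all_kept <- c(kept_case, kept_ctrl)
  dosage <- do.call(rbind, lapply(all_kept, `[[`, "dosage"))
  cov <- do.call(rbind, lapply(all_kept, `[[`, "cov"))
  ancestry <- do.call(rbind, lapply(all_kept, `[[`, "ancestry"))
  bh <- lapply(seq_along(cfg$ld_blocks), function(bi)
    do.call(rbind, lapply(all_kept, function(k) k$block_haps[[bi]])))
  status <- c(rep("case", cfg$n_cases), rep("control", cfg$n_controls))

  ids <- sprintf("S%04d", seq_len(need))
  pheno <- phenotype_table(data.frame(
    sample_id = ids, status = status,
    age = cov$age, bmi = cov$bmi,
    anc_eur = ancestry[, 1L], anc_afr = ancestry[, 2L],
    anc_nat = ancestry[, 3L],
    ses = cov$ses, education = cov$education,
    stringsAsFactors = FALSE))

  # orient metadata by planted (ancestral-mixture) frequency; read_ped_map
  # re-orients by observed counts on its own
  snps <- data.frame(
    snp_id = snp_ids,
    chrom = as.character(rep(1L + (seq_len(m_tot) - 1L) %/% 12L, length.out = m_tot)),
    pos = 10000L + 1000L * seq_len(m_tot),
    allele_minor = "A", allele_major = "G",
    gene = genes, stringsAsFactors = FALSE)
  geno <- genotype_matrix(dosage, snps, ids)

  if (!is.null(cfg$seed)) set.seed(stage_seed(cfg$seed, "missingness"))
  geno <- inject_missingness(geno, cfg$missing_rate_snp,
                             cfg$missing_rate_sample)

  truth <- list(ancestry = ancestry, base_freq = fr$base,
                pop_freqs = fr$pops, block_freqs = bfr,
                block_haplotypes = bh, effects = cfg$effects,
                intercept = intercept,
                block_cols = attr_block_cols(cfg))
  list(geno = geno, pheno = pheno, truth = truth)
}

attr_block_cols <- function(cfg) {
  at <- cfg$n_snps
  lapply(cfg$ld_blocks, function(b) {
    out <- at + seq_len(b$snps); at <<- at + b$snps; out
  })
}

draw_population <- function(n, cfg, fr, bfr, snp_ids) {
  anc <- sample_ancestry(n, cfg$dirichlet_alpha)
  sim <- simulate_genotypes(anc, fr$pops, bfr)
  cov <- draw_covariates(anc, cfg$confounder_model, cfg$dirichlet_alpha)
  score <- genetic_score(sim, cfg, snp_ids)
  list(dosage = sim$dosage, block_haps = sim$block_haplotypes,
       cov = cov, ancestry = anc, score = score)
}

slice_population <- function(pop, idx) {
  list(dosage = pop$dosage[idx, , drop = FALSE],
       block_haps = lapply(pop$block_haps, function(h) h[idx, , drop = FALSE]),
       cov = pop$cov[idx, , drop = FALSE],
       ancestry = pop$ancestry[idx, , drop = FALSE])
}

#' Inject missing genotypes
#'
#' Entries go missing independently; an entry is missing with probability
#' `1 - (1 - r_snp)(1 - r_sample)` where the per-SNP and per-sample rates can
#' be elevated for designated units (to guarantee QC casualties in testing).
#'
#' @param geno a [genotype_matrix()].
#' @param missing_rate_snp,missing_rate_sample baseline rates in \[0, 1).
#' @param elevated_snps,elevated_samples ids whose rate is replaced by
#'   `elevated_rate_snp` / `elevated_rate_sample`.
#' @param elevated_rate_snp,elevated_rate_sample elevated rates.
#' @return A `genotype_matrix` with additional `NA` entries.
#' @export
inject_missingness <- function(geno, missing_rate_snp, missing_rate_sample,
                               elevated_snps = NULL, elevated_rate_snp = 0.15,
                               elevated_samples = NULL,
                               elevated_rate_sample = 0.15) {
  stopifnot(missing_rate_snp >= 0, missing_rate_snp < 1,
            missing_rate_sample >= 0, missing_rate_sample < 1)
  n <- nrow(geno$dosage); m <- ncol(geno$dosage)
  r_snp <- rep(missing_rate_snp, m)
  r_snp[geno$snps$snp_id %in% elevated_snps] <- elevated_rate_snp
  r_samp <- rep(missing_rate_sample, n)
  r_samp[geno$samples %in% elevated_samples] <- elevated_rate_sample
  p_keep <- outer(1 - r_samp, 1 - r_snp)
  miss <- matrix(stats::runif(n * m), n, m) > p_keep
  d <- geno$dosage
  d[miss] <- NA_integer_
  genotype_matrix(d, geno$snps, geno$samples)
}

#' Write a simulated dataset to disk
#'
#' Emits PED/MAP, the covariate TSV, and a JSON truth record (ancestry,
#' population frequencies, planted effects, true block haplotypes). Output is
#' byte-identical for identical configurations and seeds.
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Invisibly, the named vector of file paths.
#' @export
write_dataset <- function(dataset, dir, prefix = "sim") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(ped = file.path(dir, paste0(prefix, ".ped")),
             map = file.path(dir, paste0(prefix, ".map")),
             cov = file.path(dir, paste0(prefix, "_covariates.tsv")),
             genes = file.path(dir, paste0(prefix, "_genes.tsv")),
             truth = file.path(dir, paste0(prefix, "_truth.json")))
  write_ped_map(dataset$geno, paths["ped"], paths["map"], dataset$pheno)
  write_covariates(dataset$pheno, paths["cov"])
  utils::write.table(dataset$geno$snps[, c("snp_id", "gene")], paths["genes"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- dataset$truth
  jsonlite::write_json(
    list(base_freq = tr$base_freq,
         pop_freqs = tr$pop_freqs,
         ancestry = tr$ancestry,
         effects = tr$effects,
         intercept = tr$intercept,
         block_haplotypes = lapply(tr$block_haplotypes, function(h)
           apply(h, 1L, paste, collapse = "|"))),
    paths["truth"], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
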