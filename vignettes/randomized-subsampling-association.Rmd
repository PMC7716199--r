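---
title: "Candidate-gene association with randomized matched sub-sampling: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene association with randomized matched sub-sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdmassoc)
```

## The problem

Candidate-gene case-control studies in admixed Latin American populations
face two entangled difficulties at small sample sizes. First, individual
ancestry varies across subjects and is correlated both with allele
frequencies and with socioeconomic covariates, so naive association tests
are confounded. Second, with a few hundred subjects, a single conventional
analysis has limited power and its point estimates are fragile to the
particular composition of the case and control series. `rdmassoc`
implements a complete analysis for this setting — quality control, allelic
and covariate-adjusted SNP association, EM-based haplotype analysis,
genotype PCA and analytic power — together with a *randomized matched
sub-sampling* (RDM) procedure that quantifies how stable each association
is across many confounder-balanced subsets of the cohort. A synthetic
cohort generator with known truth drives all testing.

## Models and procedures

### Association model

Each SNP is coded additively as the count of its minor allele
($d \in \{0,1,2\}$). The adjusted analysis is the logistic regression

$$\operatorname{logit} P(\text{case}) = \beta_0 + \beta_d d +
\beta_1 \text{age} + \beta_2 \text{BMI} + \beta_3 \text{anc}_{EUR},$$

fit by iteratively reweighted least squares; $e^{\beta_d}$ is the
per-allele odds ratio and its Wald 95% CI is $e^{\beta_d \pm 1.96\,se}$.
Ancestry enters as the single European proportion: the three admixture
proportions sum to one, so including them all would make the design
singular, and in a predominantly European cohort the European fraction
carries nearly all of the structure information. The allelic test
(Pearson chi-square on the 2x2 allele-count table, no continuity
correction) is reported alongside; the Haldane–Anscombe +0.5 correction is
applied to the allelic OR only when a cell is empty. Complete cases are
used per SNP, and multiple testing is handled by Benjamini–Hochberg FDR
(via `stats::p.adjust`).

Convergence is declared when the largest score component falls below
`1e-8` or the relative log-likelihood change falls below `1e-10`, capped
at 50 iterations with step-halving. Complete separation makes the
finite-sample MLE diverge; because the floating-point likelihood plateaus
there, the fit is flagged as separated whenever any coefficient exceeds 15
in absolute value (a per-allele OR above $e^{15}$ is not a biologically
meaningful estimate), and its p-values are returned as `NA` rather than
trusted.

### Quality control

Filters run in a fixed, documented order, because attrition counts depend
on it: (1) SNPs with call rate < 90%, (2) samples with call rate < 90%
computed on the surviving SNPs, (3) SNPs with MAF < 1% on the surviving
samples. The MAF filter uses the pooled sample by default
(`maf_on = "controls"` is available). Hardy–Weinberg equilibrium is then
tested per SNP with the conditional exact test (all heterozygote counts of
the observed parity enumerated from log-factorials; plain p, no mid-p),
in controls and in cases, BH-adjusted — and *reported only*: deviation
flags genotyping problems but is not an exclusion rule here. The exact
test rather than the chi-square is used because control groups of ~160
with minor-allele counts in the tens put the chi-square approximation in
doubt.

### The RDM procedure

The RDM stage draws sub-samples of 100 cases and 108 controls without
replacement, keeps a sub-sample only if cases and controls are
indistinguishable in age (Welch t-test), education and SES (Pearson
chi-square), all at $p \ge 0.05$, and repeats until 1000 balanced
sub-samples exist (rejection sampling, budget 100x the target; exhausting
the budget is a fatal diagnostic that the cohort's confounding cannot be
matched away at these sizes). Within every sub-sample the SNP-level QC is
re-applied — a SNP too rare or too missing inside a sub-sample is simply
not evaluated there — and the adjusted logistic model is refit. A unit is
*kept* when the fraction of sub-samples with $p < 0.05$ strictly exceeds
50%. Per-unit odds ratios are summarized across sub-samples by the median
and the 2.5–97.5 percentile interval, since no aggregation rule is
canonical for this procedure.

Matching on all three variables simultaneously is the default
(`match_on` can restrict to any subset, e.g. SES only). Balance is
defined by testing, not by caliper matching: this is deliberately the
procedure's own logic — sub-samples are random, so retained associations
cannot be artifacts of one particular matched construction.

Under a genetic null the per-sub-sample rejection rate concentrates near
the test level (sub-samples overlap, which correlates their p-values but
does not bias the rate under exchangeability). The >50% keep rule,
however, is a stability criterion, not a multiplicity correction: because
each sub-sample contains ~60% of the cohort, its test statistic is ~77%
correlated with the full-sample one ($\rho = \sqrt{n_{sub}/n}$), so a
chance full-sample association at $p \lesssim 0.01$ — expected about once
per hundred null SNPs — remains significant in most sub-samples
and is kept. RDM support certifies that a signal is not an artifact of
confounder composition; genome-wise error control still comes from the
FDR of the conventional analysis.

### Haplotypes

Genes whose SNPs show significant pairwise LD (chi-square on
$2n\,r^2$ with 1 df, BH-adjusted within gene at 0.05 — no threshold is
canonical, so the screen is a configuration knob) get a haplotype
analysis. Haplotype frequencies are estimated from unphased genotypes by
the standard EM under haplotype-level Hardy–Weinberg: E-step posteriors
over compatible diplotypes proportional to $f_{h_1} f_{h_2}$ (x2 when
heterozygous), M-step frequency updates, uniform initialization over
compatible haplotypes, convergence at max frequency change `1e-8` or 1000
iterations. Frequencies are reported from per-group EM runs (cases,
controls), but the per-individual *expected haplotype dosages* used for
association come from the pooled, phenotype-blind EM — using group-specific
dosages would leak the outcome into the predictor. Association is
one-vs-rest adjusted logistic regression per haplotype on expected dosage
(posterior-mean dosage propagates phase uncertainty; best-guess phase
would not), with haplotypes below 1% pooled frequency merged into a
"rare" class. The haplotype RDM re-runs the EM inside every sub-sample
and matches haplotypes across sub-samples by allele string.

### Structure and power

Genotype PCA standardizes each SNP by its estimated allele frequency
(center $2\hat p$, scale $\sqrt{2\hat p(1-\hat p)}$), mean-imputes
missing dosages (adequate at ~1% missingness; it shrinks structure
slightly but cannot create it), and takes the SVD with a deterministic
sign convention. Power uses the normal approximation for the two-sided
two-proportion test at Cohen's standardized effect
$h = 2\arcsin\sqrt{p_1} - 2\arcsin\sqrt{p_2}$ with the harmonic-mean
sample size $\tilde n = 2n_1n_2/(n_1+n_2)$:
$\Phi(h\sqrt{\tilde n/2} - z_{1-\alpha/2}) +
\Phi(-h\sqrt{\tilde n/2} - z_{1-\alpha/2})$. The "effect size 0.26" of
the design evaluation is interpreted as Cohen's h — the convention of the
standard power tooling for proportions; at $\alpha = 0.05$ with 172 cases
and 160 controls this gives about 66%, below the conventional 80% and
below the 70% the design discussion cites as a bound.

## The synthetic cohort generator

The generator emulates the features of the target setting that the
analysis must survive, with known truth for parameter-recovery testing:

* **Admixture.** Per-individual (EUR, AFR, NAT) proportions are
  Dirichlet(16, 2, 2): mean European fraction 0.80 with most mass in
  0.6–0.95, matching the predominantly European urban admixed populations
  the design targets.
* **Allele frequencies.** Balding–Nichols: ancestral frequency uniform in
  [0.05, 0.5]; each parental population draws from
  $\mathrm{Beta}(p\frac{1-F}{F}, (1-p)\frac{1-F}{F})$ with $F = 0.1$
  (continental-scale divergence). Gametes are Bernoulli at the
  ancestry-weighted mixture frequency.
* **LD blocks.** Whole-block haplotypes drawn per gamete from
  population-specific haplotype frequencies, themselves perturbed on the
  simplex by a Dirichlet with concentration $\frac{1-F}{F} f$ — the
  Balding–Nichols idea applied to haplotypes. Defaults: two 2-SNP blocks
  and one 3-SNP block with common haplotypes.
* **Confounders.** SES and education are 3-level ordinals from
  thresholded latent Gaussians loading on the European proportion
  (loadings 1.5 and 1.0; cutpoints set for roughly equal thirds at the
  population ancestry distribution); BMI is
  $N(26 - 2\,\text{anc}_{EUR}, 4^2)$ kg/m²; age is $N(60, 8^2)$ years
  truncated below at 45 (a post-menopausal cohort).
* **Outcome.** Case probability is logistic in the planted SNP/haplotype
  effects plus log-ORs of SES (+0.2/level), education (−0.15/level) and
  age (+0.02/year) — the covariate imbalance the RDM stage must remove.
  The intercept is solved numerically so the population case rate is 10%
  before enrichment, and cases/controls are collected by rejection from a
  population stream (retrospective sampling, so the planted log-OR is
  exactly the estimand of the logistic analysis). Default sizes are 176
  cases and 183 controls, the pre-QC scale of the target design.
* **Planted effects.** Defaults: ORs 1.5, 1.9 and 0.5 on three SNPs and
  1.75 on one block haplotype — the moderate effect range candidate-gene
  studies of this size report.
* **Missingness.** Independent per-entry, 1% per SNP and 0.5% per sample
  by default, with designated units available at elevated rates to
  guarantee QC casualties in tests.

What the generator does *not* emulate: genotyping-error-driven HWE
violations, relatedness, batch effects, recombination-map-realistic LD, or
X-linked dosage. Passing tests therefore certify the statistical machinery
under the stated model, not robustness to artifacts the model omits.

## Numerical and design choices

* Minor-allele ties (MAF exactly 0.5) break alphabetically; monomorphic
  SNPs keep the observed allele as major with a placeholder minor — both
  for determinism, and such SNPs fall at QC anyway.
* One missing allele in a PED pair voids the whole genotype (PLINK
  semantics).
* RNG: the generator derives one seed per logical stage (frequencies,
  population stream, missingness) from the master seed, so changing, say,
  the missingness rate leaves genotypes untouched. Within the population
  stream, ancestry, genotypes, covariates and status are drawn from a
  single stream: splitting them per stage would desynchronize the
  per-individual draws under rejection sampling.
* The matching feasibility of the RDM stage depends on the realized
  confounding of the particular cohort: at SES-status log-ORs around 0.4
  per level, occasional cohorts realize imbalance strong enough that
  balanced sub-samples of 100+108 become one-in-a-hundred events, which
  the 100x rejection budget deliberately treats as a fatal diagnostic
  rather than silently producing a biased ensemble. The null-calibration
  studies in the test suite use 0.25 per level — clear cohort-level
  confounding with feasible matching, the regime the procedure is meant
  for — and the study's own ensemble size of 1000.
* Degenerate inputs: all-missing SNPs are an error at MAF computation; a
  covariate constant within a sub-sample is treated as balanced (with a
  warning) since its test carries no information; SNPs monomorphic within
  a sub-sample are not evaluated there; EM sets with no complete
  individual are an error.

## Problem sizes used in the checks

The test suite runs the full RDM null calibration at 20 replicate cohorts
x 1000 sub-samples x 50 SNPs, parameter recovery at 200 replicates
(n = 10,000 for the SNP effect; n = 332 for the haplotype effect), the
exhaustive HWE oracle sweep over every genotype table with $n \le 50$,
and 25-dataset EM-vs-grid-search comparisons; these sizes make the whole
suite complete in well under half an hour on one CPU while keeping
Monte-Carlo error far below the tested margins.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1L)
ds <- simulate_dataset(cfg)
qc <- apply_filters(ds$geno, ds$pheno, run_config())
scan <- run_scan(qc$geno, ds$pheno)
ens <- build_ensemble(ds$pheno, run_config(seed = 2L))
rdm <- rdm_scan(qc$geno, ds$pheno, ens, run_config())
association_report(scan, qc$geno, rdm)
```

The `analysis/` directory of the repository runs exactly this workflow
stage by stage (simulation, QC, association, RDM, haplotypes,
structure/power) and writes its tables under `results/`.

## Known limitations

* Wald CIs and p-values degrade for very rare haplotypes; the 1% pooling
  threshold bounds but does not eliminate this.
* The RDM keep rule is a stability heuristic, not a calibrated test; its
  nominal properties are characterized only by simulation.
* Expected-dosage haplotype association slightly attenuates very strong
  effects when phase uncertainty is high (r² between block SNPs low).
* PCA mean-imputation assumes missingness unrelated to structure.
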