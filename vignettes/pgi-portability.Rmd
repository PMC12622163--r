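---
title: "Cross-ancestry portability of polygenic indexes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-ancestry portability of polygenic indexes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Polygenic indexes (PGIs) — weighted sums of allele counts with weights from a
discovery GWAS — lose predictive power when the discovery and target samples
come from different genetic ancestries. `pgiport` quantifies that loss and
decomposes it. Three quantities organize everything the package does:

* **Observed relative accuracy.** For a phenotype $y$ residualized on
  demographic covariates, the incremental $R^2$ of a PGI is the gain in the
  coefficient of determination when the PGI is added to a regression of $y$
  on principal-component (and optionally batch) covariates. The observed
  relative accuracy in target ancestry $i$ is
  $$\mathrm{RA}^{\mathrm{obs}}_i = R^2_i / R^2_{\mathrm{ref}},$$
  the ratio of the target-ancestry incremental $R^2$ to the reference
  (discovery-ancestry) incremental $R^2$.

* **Expected relative accuracy.** Under a model in which each PGI-SNP $k$
  tags a set of *candidate causal SNPs* (QC-passing variants within 100 kb
  with $r^2 > 0.45$ to $k$ in the discovery-ancestry reference panel), with
  causal effects drawn independently with cross-population correlation
  $\rho_b$ and ancestry-specific heritabilities $h_1^2, h_2^2$:
  $$\mathrm{RA}^{\mathrm{exp}} = \frac{\rho_b^2 h_2^2}{h_1^2}
   \times
   \frac{\Big(\sum_k \overline{r_{k,1} r_{k,2}}\,
         \sqrt{p_{k,2} q_{k,2}/(p_{k,1} q_{k,1})}\Big)^2}
        {\Big(\sum_k \overline{r^2_{k,1}}\Big)^2}
   \times
   \frac{\sum_k p_{k,1} q_{k,1} \hat\beta_k^2}
        {\sum_k p_{k,2} q_{k,2} \hat\beta_k^2},$$
  where $\overline{r^2_{k,1}}$ is the mean squared allele-count correlation
  between PGI-SNP $k$ and its candidates in population 1,
  $\overline{r_{k,1} r_{k,2}}$ the mean product of the population-1 and
  population-2 correlations, $p_{k,i}$ the allele frequency of $k$ in
  population $i$ ($q = 1-p$; the $pq$ terms are invariant to which allele is
  labelled minor), and $\hat\beta_k$ the discovery marginal effect. The
  effects factor $\rho_b^2 h_2^2/h_1^2$ is fixed at 1 unless heritability
  inputs are supplied.

* **Explained loss.** For phenotypes whose observed relative accuracy is
  statistically below one (95% bootstrap CI upper bound < 1),
  $$\mathrm{LoA} = \frac{1-\mathrm{RA}^{\mathrm{exp}}}
                        {1-\mathrm{RA}^{\mathrm{obs}}} \times 100\%$$
  is the share of the observed accuracy loss explained by the model — by
  LD/MAF differences alone, or by LD/MAF plus heritability when
  $\mathrm{RA}^{\mathrm{exp}}$ is multiplied by the target/reference
  heritability ratio. Values above 100% are reported as computed: they say
  the observed loss is *smaller* than LD/MAF differences alone predict.

## Resolving the bracketing of the expectation

The two LD sums in $\mathrm{RA}^{\mathrm{exp}}$ are *each squared*. This is
not a free choice: writing $R^2_i = \mathrm{cov}(\mathrm{PGI}, y_i)^2 /
(\mathrm{var}(\mathrm{PGI}_i)\,\mathrm{var}(y_i))$, the covariance is a sum
over SNPs that enters squared, producing the outer squares on both the
numerator and denominator LD sums, while the PGI variance supplies the
unsquared $\sum_k p_{k,i} q_{k,i} \hat\beta_k^2$ terms. The package fixes the
bracketing with an exact one-tag/one-causal oracle: for a single tag SNP with
correlations $r_1, r_2$ to a single causal SNP, the closed-form out-of-sample
$R^2$ ratio is $(r_2^2/r_1^2)(h_2^2/h_1^2)$, independent of the tag
frequencies. Only the both-sums-squared bracketing reproduces this identity —
the tag-frequency terms then cancel exactly between the LD/MAF factor and the
variance-scale factor, which the test grid verifies over
$r_1, r_2 \in \{0.3, 0.6, 0.9\}$ and frequencies $\{0.1, 0.3, 0.5\}$ to
$10^{-8}$.

## The synthetic two-population generator

Real analyses of this kind use access-restricted biobank genotypes. The
generator (`sim_config()`, `simulate_reference_panel()` and friends) creates
two-population cohorts with the statistical structure the analysis assumes,
so every stage is testable end to end.

* **Frequencies.** One ancestral frequency per LD block, uniform on
  $[\mathrm{maf\_floor}, 1-\mathrm{maf\_floor}]$; population block
  frequencies from the Balding–Nichols beta distribution with parameter
  $F_{st}$; a small per-variant Balding–Nichols jitter
  (`within_block_fst = 0.01`) around the population block frequency.
  Divergence acts at the block level because linked variants share their
  drift history on real haplotypes; if each variant drifted independently,
  linked variants would have mismatched frequencies and the binary
  correlations within a block could never reach the $r^2 > 0.45$ range the
  candidate definition requires.
* **LD.** Within each block, haplotypes follow a first-order Markov
  (Gaussian-copula) process with adjacent latent correlation
  `block_ld_rho`, independent across blocks; a diploid dosage is the sum of
  two haplotypes. The LD strength is population-specific, default
  `c(0.95, 0.65)`: the target population has markedly shorter-range LD, as
  African-ancestry populations do relative to a European reference. This
  asymmetry — not allele-frequency drift alone — is what produces a
  substantial, realistic portability loss.
* **Architecture.** `causal_clustering = "block"` (default) samples whole
  LD blocks uniformly without replacement and makes every variant in a
  sampled block causal. This dense local architecture is exactly the regime
  the expectation above models: every strong-LD neighbour of a sentinel is
  potentially causal. With a single isolated causal variant per block
  (`"uniform"`, also provided), the sentinel is selected as the causal
  variant's best tag, so the candidate average is structurally optimistic
  and the expectation is not an unbiased predictor of the observed ratio —
  a model limitation, not an implementation artifact. Effects are bivariate
  normal across populations with correlation `rho_b`, rescaled so the
  realized genetic variance matches `h2_pop1`/`h2_pop2` exactly.
* **Discovery GWAS.** Marginal effects are computed analytically from
  within-block reference LD (population LD is block-diagonal by
  construction) and perturbed with sampling noise of standard error
  $1/\sqrt{2pq\,n_{\mathrm{discovery}}}$ on the per-allele scale.
  Restricting the analytic effects to within-block LD matters: estimating
  them from full-panel sample correlations would share cross-block sampling
  noise with the target cohort, a sample-overlap artifact impossible in the
  real three-cohort (discovery / LD reference / target) design.
* **Confounding.** `confound_strength` adds an environmental gradient,
  aligned with the cross-population frequency-difference axis, to the
  population-1 phenotype, and biases standard-mode discovery betas along the
  same axis. Family-mode summary statistics are unbiased but carry
  `family_se_inflation = 1.6` times the standard error, emulating the
  smaller effective sample size of within-family designs — an emulation of
  the contrast, not a pedigree simulation. Only the stratification channel
  of standard-GWAS confounding is emulated; gene–environment correlation
  via parental genotypes and assortative mating are not.

Default study conditions (fixed once, used by the acceptance tests and
script): 5,000 variants in 1,250 four-variant blocks, 2,000 samples per
population, 200 causal variants (50 blocks), $F_{st} = 0.15$,
$\rho_b = 1$, $h^2 = 0.5$, discovery size $10^5$, top-200 index SNPs.
At that size one end-to-end replicate takes on the order of ten seconds, and
the replication counts (20 cohorts for the recovery studies, 200 scaled-down
cohorts for test calibration) were chosen so Monte-Carlo error is small
relative to the tolerances being checked.

## Inference machinery and its calibration

* **Bootstrap.** Percentile CIs with 1,000 replications by default;
  relative-accuracy CIs resample target- and reference-ancestry individuals
  independently (the two incremental $R^2$ come from disjoint samples).
  Negative incremental-$R^2$ replicates propagate unmodified, so CIs can
  include negative values.
* **Paired test.** The standard-vs-family comparison resamples the *same*
  individuals for both PGIs in every replicate;
  $p = 2\min(\Pr^*[\Delta \le 0], \Pr^*[\Delta \ge 0])$ clamped to
  $[2/B, 1]$. The test is conditional on the realized pair of weight
  vectors. Its type-I calibration is therefore assessed on exchangeable
  populations ($F_{st} = 0$, equal LD, no jitter), where the conditional
  relative accuracy of *any* fixed PGI is exactly 1 in both populations and
  the test's null holds exactly. When the populations differ, two
  independently noisy weightings genuinely differ in conditional relative
  accuracy — per-SNP weight noise transfers differently through the two LD
  structures — and rejections of that (true) difference are correct
  behaviour, not miscalibration.
* **Jackknife.** Cross-phenotype means are summarized with the
  leave-one-out jackknife SE, which equals $s/\sqrt{n}$ exactly for the
  mean.
* **Welch ANOVA and BH.** `welch_anova()` wraps `stats::oneway.test()`
  (heteroscedastic $F$, Satterthwaite df); `bh_adjust()` wraps
  `stats::p.adjust(method = "BH")` and adds rejection flags.
* **Delta method.** The SE of the explained-loss percentage treats
  $\mathrm{RA}^{\mathrm{obs}}$ and $\mathrm{RA}^{\mathrm{exp}}$ as
  independent — they are computed from disjoint data (target-cohort
  regressions versus reference-panel LD with discovery betas):
  $\mathrm{SE} = 100\sqrt{\big(\tfrac{s_e}{1-a}\big)^2 +
  \big(\tfrac{(1-e)\,s_a}{(1-a)^2}\big)^2}$ with $a, e$ the observed and
  expected relative accuracies. The heritability adjustment propagates the
  three relative variances in quadrature, likewise under independence.
  Cross-cohort comparisons use a log-scale $Z$ with BH correction across
  phenotypes.

## Numerical and convention choices

* Coordinates are 1-based inclusive; BED region inputs (0-based half-open)
  are converted internally. All kb windows are symmetric and
  endpoint-inclusive.
* Allele alignment matches by variant id, reconciles strand by
  complementation, flips signs (and `eaf`) when the effect allele is the
  panel's other allele, and drops A/T and C/G variants by default (the two
  strand readings are indistinguishable); aligning an aligned table is a
  no-op.
* Missing dosages are stored explicitly and mean-imputed only inside
  scoring and LD computation. PGI standardization uses the population
  ($1/n$) standard deviation within the analysis sample.
* Clump and prune ties are broken deterministically (ascending p, then
  variant id; left-to-right within pruning windows).
* Residualization centers covariates before taking polynomial powers (raw
  third powers of calendar years would defeat the QR rank checks), uses the
  regression-complete subsample for within-wave standardization, averages
  each sample's available wave residuals, and returns zero residuals with a
  warning when the covariates fit perfectly. Binary phenotypes pass through
  the same linear (OLS) pipeline — a linear-probability treatment.
* Samples matching several ancestries within the 4-SD windows are assigned
  to the smallest standardized Euclidean distance; relatedness-pair removal
  drops the member with higher missingness, then the lexicographically
  larger id.
* The exact Hardy–Weinberg test is evaluated on rounded hard calls, for
  that filter only.

## What passing tests do and do not show

The generator reproduces the *structure* the analysis assumes: independent
blocks, block-coherent drift, copula LD, additive effects, Gaussian noise.
Real data differ in ways the simulations do not probe: long-range and
overlapping LD, allele-frequency-dependent architectures, uncorrected
population structure within ancestry groups, binary traits with low
prevalence, imputation dosage error, and candidate sets that miss untyped
causal variants. Passing the recovery tests shows the estimator chain is
internally consistent under the model's own assumptions; it does not certify
the model's adequacy for any particular real trait. The `"uniform"`
architecture option exists precisely to demonstrate a regime where the
expectation is biased upward even though every component is computed
correctly.
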