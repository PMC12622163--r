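#' Run the full synthetic portability pipeline once
#'
#' Simulates a two-population cohort under `config`, emulates a discovery
#' GWAS in population 1, builds a PGI from the clumped top index SNPs, and
#' computes both the observed relative accuracy of the PGI in population 2
#' (population 1 being the reference) and the expected relative accuracy
#' from the cross-population LD/MAF summaries of the same SNP set. This is
#' the end-to-end experiment used to check that the theoretical model
#' recovers the simulated truth.
#'
#' Clumping is restricted to QC-passing shared variants, so the PGI-SNP set
#' entering the expected-accuracy sums coincides with the scored SNPs. By
#' default the causal variants themselves are excluded from the discovery
#' summary statistics (and hence from the PGI), emulating the typical
#' situation where causal variants are not among the genotyped PGI-SNPs and
#' the sentinel SNP is a tag; they remain in the reference panels and in the
#' candidate causal pool.
#'
#' @param config a [sim_config()].
#' @param set_size top index-SNP set size used for the PGI and the model
#'   (default 200).
#' @param mode discovery GWAS mode, `"standard"` or `"family"`.
#' @param B bootstrap replications for the observed-RA CI (default 400).
#' @param effects_factor multiplier for [expected_ra()] (default 1).
#' @param exclude_causal_from_pgi drop causal variants from the discovery
#'   summary statistics before clumping and scoring (default `FALSE`).
#' @return list: `ra` (an `ra_estimate` row), `expected` (an `expected_ra`),
#'   `ra_obs`, `ra_expected`, `n_index`, `sumstats`, `top_ids`.
#' @export
portability_experiment <- function(config, set_size = 200,
                                   mode = c("standard", "family"),
                                   B = 400, effects_factor = 1,
                                   exclude_causal_from_pgi = FALSE) {
  mode <- match.arg(mode)
  panel <- simulate_reference_panel(config)
  causal <- simulate_causal_architecture(panel, config)
  phen <- simulate_phenotypes(panel, causal, config)
  ss <- simulate_discovery_sumstats(panel, causal, config, mode)
  pop1 <- subset_panel(panel, samples = panel$ancestry == "POP1")
  pop2 <- subset_panel(panel, samples = panel$ancestry == "POP2")
  qc <- qc_common_snps(list(pop1, pop2))
  ssq <- ss[ss$id %in% qc, , drop = FALSE]
  if (exclude_causal_from_pgi)
    ssq <- ssq[!ssq$id %in% causal$causal_ids, , drop = FALSE]
  cl <- clump(ssq, pop1)
  top <- suppressWarnings(top_snps(cl, set_size))
  cand <- select_candidate_causal(top, pop1, qc)
  lds <- ld_summaries(
    data.frame(id = top, beta_hat = ssq$beta[match(top, ssq$id)]),
    cand, pop1, pop2)
  expct <- expected_ra(lds, effects_factor, snp_set_size = set_size)
  weights <- derive_weight_table(ssq[ssq$id %in% top, , drop = FALSE])
  pgi <- compute_pgi(panel, weights)
  df <- data.frame(y = phen$value[match(panel$samples, phen$sample_id)],
                   pgi = pgi$raw, ancestry = panel$ancestry,
                   stringsAsFactors = FALSE)
  ra <- estimate_ra_obs(df, target = "POP2", ref = "POP1", B = B,
                        seed = config$seed + 7L)
  list(ra = ra, expected = expct, ra_obs = ra$ra_obs,
       ra_expected = expct$ra_expected, n_index = length(top),
       sumstats = ssq, top_ids = top)
}

#' Repeat the portability experiment over seeds and decompose the loss
#'
#' Runs [portability_experiment()] for `n_seeds` consecutive seeds, averages
#' the observed and expected relative accuracies, and computes the share of
#' the observed accuracy loss explained by the LD/MAF model (and, when
#' heritabilities are supplied, by LD/MAF plus heritability).
#'
#' @param config a [sim_config()]; its `seed` is the first seed used.
#' @param n_seeds number of independent replicates (default 20).
#' @param set_size,mode,B,effects_factor,... passed to
#'   [portability_experiment()].
#' @param h2_inputs optional list with `target` and `ref` heritability rows
#'   (`h2`, `se`) for the heritability-adjusted variant.
#' @return list: per-seed `ra_obs` and `ra_expected`, their means and SEs
#'   (across-seed SD of the mean), `loa_ld_maf` (percent), and when
#'   `h2_inputs` is given `ra_expected_h2` and `loa_ld_maf_h2`.
#' @export
portability_study <- function(config, n_seeds = 20, set_size = 200,
                              mode = "standard", B = 200,
                              effects_factor = 1, h2_inputs = NULL, ...) {
  ra_obs <- ra_exp <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- config
    cfg$seed <- config$seed + (i - 1L)
    ex <- portability_experiment(cfg, set_size = set_size, mode = mode,
                                 B = B, effects_factor = effects_factor, ...)
    ra_obs[i] <- ex$ra_obs
    ra_exp[i] <- ex$ra_expected
  }
  m_obs <- mean(ra_obs); m_exp <- mean(ra_exp)
  se_obs <- stats::sd(ra_obs) / sqrt(n_seeds)
  se_exp <- stats::sd(ra_exp) / sqrt(n_seeds)
  out <- list(ra_obs = ra_obs, ra_expected = ra_exp,
              ra_obs_mean = m_obs, ra_expected_mean = m_exp,
              ra_obs_se = se_obs, ra_expected_se = se_exp)
  if (m_obs < 1) {
    out$loa_ld_maf <- compute_loa(m_obs, m_exp)
    out$loa_ld_maf_se <- loa_se_delta(m_obs, se_obs, m_exp, se_exp)$se
  }
  if (!is.null(h2_inputs)) {
    adj <- adjust_for_h2(m_exp, h2_inputs$target, h2_inputs$ref,
                         se_expected = se_exp)
    out$ra_expected_h2 <- adj$ra_expected
    out$ra_expected_h2_se <- adj$se
    if (m_obs < 1) {
      out$loa_ld_maf_h2 <- compute_loa(m_obs, adj$ra_expected)
      out$loa_ld_maf_h2_se <- loa_se_delta(m_obs, se_obs, adj$ra_expected,
                                           adj$se)$se
    }
  }
  out
}

#' Standard versus family-based PGI contrast on one synthetic cohort
#'
#' Builds a standard-mode PGI (whose discovery betas carry the
#' stratification bias when `confound_strength > 0`) and a family-mode PGI
#' (unbiased, noisier) on the same simulated cohort, each from its own
#' clumped top index-SNP set, and compares their observed relative
#' accuracies with the paired bootstrap test (same resampled individuals
#' for both PGIs in every replicate).
#'
#' @param config a [sim_config()].
#' @param set_size top index-SNP set size per mode (default 200).
#' @param B bootstrap replications (default 200).
#' @return list: `r2_ref_standard`, `r2_ref_family`, `ra_standard`,
#'   `ra_family`, `delta_ra` (family minus standard), `p_value`.
#' @export
family_standard_contrast <- function(config, set_size = 200, B = 200) {
  panel <- simulate_reference_panel(config)
  causal <- simulate_causal_architecture(panel, config)
  phen <- simulate_phenotypes(panel, causal, config)
  pop1 <- subset_panel(panel, samples = panel$ancestry == "POP1")
  pop2 <- subset_panel(panel, samples = panel$ancestry == "POP2")
  qc <- qc_common_snps(list(pop1, pop2))
  one_pgi <- function(mode) {
    ss <- simulate_discovery_sumstats(panel, causal, config, mode)
    ssq <- ss[ss$id %in% qc, , drop = FALSE]
    cl <- clump(ssq, pop1)
    top <- suppressWarnings(top_snps(cl, set_size))
    w <- derive_weight_table(ssq[ssq$id %in% top, , drop = FALSE])
    compute_pgi(panel, w)$raw
  }
  df <- data.frame(y = phen$value[match(panel$samples, phen$sample_id)],
                   pgi_a = one_pgi("family"), pgi_b = one_pgi("standard"),
                   ancestry = panel$ancestry, stringsAsFactors = FALSE)
  ts <- paired_bootstrap_ra_test(df, target = "POP2", ref = "POP1",
                                 B = B, seed = config$seed + 11L)
  d1 <- df[df$ancestry == "POP1", ]; d2 <- df[df$ancestry == "POP2", ]
  r2rs <- .inc_r2(d1$y, d1$pgi_b); r2rf <- .inc_r2(d1$y, d1$pgi_a)
  list(r2_ref_standard = r2rs, r2_ref_family = r2rf,
       ra_standard = .inc_r2(d2$y, d2$pgi_b) / r2rs,
       ra_family = .inc_r2(d2$y, d2$pgi_a) / r2rf,
       delta_ra = ts$delta_ra, p_value = ts$p_value)
}

#' Null experiment for paired relative-accuracy test calibration
#'
#' Builds two PGIs that are exchangeable by construction — the same top
#' index-SNP set (ranked on the noiseless analytic discovery effects, so
#' the set choice favours neither) with two independent, equal-variance
#' discovery noise draws — and applies the paired bootstrap test. The
#' population relative accuracies of the two PGIs are equal up to the
#' (second-order) effect of the weight noise, so rejections at level alpha
#' should occur at rate alpha.
#'
#' @param config a [sim_config()].
#' @param set_size top index-SNP set size (default 40).
#' @param B bootstrap replications (default 100).
#' @return list `delta_ra`, `p_value`.
#' @export
paired_null_experiment <- function(config, set_size = 40, B = 100) {
  panel <- simulate_reference_panel(config)
  causal <- simulate_causal_architecture(panel, config)
  phen <- simulate_phenotypes(panel, causal, config)
  pop1 <- subset_panel(panel, samples = panel$ancestry == "POP1")
  pop2 <- subset_panel(panel, samples = panel$ancestry == "POP2")
  qc <- qc_common_snps(list(pop1, pop2))
  cfg_b <- config
  cfg_b$seed <- config$seed + 104729L   # independent second noise draw
  ss_a <- simulate_discovery_sumstats(panel, causal, config, "standard")
  ss_b <- simulate_discovery_sumstats(panel, causal, cfg_b, "standard")
  ss_a$analytic <- attr(ss_a, "analytic_beta_std")
  # symmetric set choice: clump on the noiseless analytic ranking
  ssr <- ss_a[ss_a$id %in% qc, , drop = FALSE]
  ssr$pval <- stats::pnorm(-abs(ssr$analytic) * sqrt(config$n_discovery)) * 2
  ssr$pval <- pmax(ssr$pval, .Machine$double.xmin)
  top <- suppressWarnings(top_snps(clump(ssr, pop1), set_size))
  pgi_of <- function(ss) {
    w <- derive_weight_table(ss[ss$id %in% top, , drop = FALSE])
    compute_pgi(panel, w)$raw
  }
  df <- data.frame(y = phen$value[match(panel$samples, phen$sample_id)],
                   pgi_a = pgi_of(ss_a), pgi_b = pgi_of(ss_b),
                   ancestry = panel$ancestry, stringsAsFactors = FALSE)
  ts <- paired_bootstrap_ra_test(df, target = "POP2", ref = "POP1",
                                 B = B, seed = config$seed + 13L)
  list(delta_ra = ts$delta_ra, p_value = ts$p_value)
}
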