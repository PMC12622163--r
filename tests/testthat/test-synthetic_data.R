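test_that("generator operations are deterministic given the config", {
  cfg <- small_config(seed = 11)
  p1 <- simulate_reference_panel(cfg)
  p2 <- simulate_reference_panel(cfg)
  expect_identical(p1$dosages, p2$dosages)
  c1 <- simulate_causal_architecture(p1, cfg)
  c2 <- simulate_causal_architecture(p2, cfg)
  expect_identical(c1$beta_pop1, c2$beta_pop1)
  y1 <- simulate_phenotypes(p1, c1, cfg)
  y2 <- simulate_phenotypes(p2, c2, cfg)
  expect_identical(y1$value, y2$value)
  s1 <- simulate_discovery_sumstats(p1, c1, cfg, "standard")
  s2 <- simulate_discovery_sumstats(p2, c2, cfg, "standard")
  expect_identical(s1$beta, s2$beta)
})

test_that("fst = 0 gives vanishing frequency divergence, fst = 0.1 matches Hudson", {
  cfg0 <- small_config(fst = 0, within_block_fst = 0, n_samples_per_pop = 1500,
                       seed = 3)
  pan0 <- suppressMessages(simulate_reference_panel(cfg0))
  f1 <- colMeans(pan0$dosages[pan0$ancestry == "POP1", ]) / 2
  f2 <- colMeans(pan0$dosages[pan0$ancestry == "POP2", ]) / 2
  expect_lt(mean(abs(f1 - f2)), 0.02)

  cfg <- sim_config(n_variants = 2000, n_blocks = 500, fst = 0.1,
                    within_block_fst = 0, n_samples_per_pop = 2000,
                    block_ld_rho = 0, seed = 4)
  pan <- simulate_reference_panel(cfg)
  n <- cfg$n_samples_per_pop
  g1 <- colMeans(pan$dosages[pan$ancestry == "POP1", ]) / 2
  g2 <- colMeans(pan$dosages[pan$ancestry == "POP2", ]) / 2
  expect_lt(abs(hudson_fst(g1, g2, 2 * n, 2 * n) - 0.1), 0.02)
})

test_that("block_ld_rho = 0 gives independence-level adjacent r2", {
  cfg <- small_config(block_ld_rho = 0, n_samples_per_pop = 500, seed = 5)
  pan <- simulate_reference_panel(cfg)
  pop1 <- subset_panel(pan, samples = pan$ancestry == "POP1")
  Z <- imputed_std(pop1)
  n <- nrow(Z)
  blk <- rep(seq_len(cfg$n_blocks), each = cfg$n_variants / cfg$n_blocks)
  adj <- which(diff(blk) == 0)
  r2 <- sapply(adj, function(j) (sum(Z[, j] * Z[, j + 1]) / (n - 1))^2)
  expect_lt(abs(mean(r2) - 1 / n), 1.5 / n)
})

test_that("cross-population effect correlation honours rho_b", {
  cfg <- small_config(rho_b = 1, seed = 7, causal_clustering = "uniform")
  pan <- simulate_reference_panel(cfg)
  cm <- simulate_causal_architecture(pan, cfg)
  # rho_b = 1: effects proportional across populations
  expect_equal(cor(cm$beta_pop1, cm$beta_pop2), 1, tolerance = 1e-12)

  cfg0 <- sim_config(n_variants = 5000, n_blocks = 1250, n_causal = 5000,
                     n_samples_per_pop = 50, rho_b = 0,
                     causal_clustering = "uniform", seed = 8)
  pan0 <- simulate_reference_panel(cfg0)
  cm0 <- simulate_causal_architecture(pan0, cfg0)
  expect_equal(cor(cm0$raw_beta_pop1, cm0$raw_beta_pop2), 0, tolerance = 0.05)
})

test_that("single causal variant has the closed-form genetic variance", {
  cfg <- small_config(n_causal = 1, h2_pop1 = 0.4, h2_pop2 = 0.4, seed = 9,
                      causal_clustering = "uniform")
  pan <- simulate_reference_panel(cfg)
  cm <- simulate_causal_architecture(pan, cfg)
  for (pop in c("POP1", "POP2")) {
    rows <- pan$ancestry == pop
    x <- pan$dosages[rows, cm$causal_idx]
    b_std <- if (pop == "POP1") cm$beta_pop1 else cm$beta_pop2
    # per-allele effect = b_std / sd(x); realized genetic variance must be
    # beta_allele^2 * var(x) = b_std^2 = target h2 by the rescaling contract
    expect_equal(b_std^2, 0.4, tolerance = 1e-10)
    expect_equal(var(x * (b_std / sd(x))), 0.4, tolerance = 1e-10)
  }
})

test_that("realized phenotype heritability matches the target", {
  cfg <- sim_config(n_variants = 500, n_blocks = 125, n_causal = 100,
                    n_samples_per_pop = 2500, h2_pop1 = 0.5, h2_pop2 = 0.5,
                    seed = 10)
  pan <- simulate_reference_panel(cfg)
  cm <- simulate_causal_architecture(pan, cfg)
  ph <- simulate_phenotypes(pan, cm, cfg)
  y <- ph$value[match(pan$samples, ph$sample_id)]
  for (pop in c("POP1", "POP2")) {
    rows <- pan$ancestry == pop
    r2 <- summary(lm(y[rows] ~ cm$genetic_score[rows]))$r.squared
    expect_lt(abs(r2 - 0.5), 0.05)
  }
  # null heritability: phenotype carries no genetic signal
  cfg0 <- small_config(h2_pop1 = 0, h2_pop2 = 0, seed = 10)
  pan0 <- simulate_reference_panel(cfg0)
  cm0 <- simulate_causal_architecture(pan0, cfg0)
  ph0 <- simulate_phenotypes(pan0, cm0, cfg0)
  y0 <- ph0$value[match(pan0$samples, ph0$sample_id)]
  g0 <- drop(imputed_std(pan0)[, cm0$causal_idx] %*% cm0$raw_beta_pop1)
  expect_lt(summary(lm(y0 ~ g0))$r.squared, 0.02)
})

test_that("discovery betas converge to the analytic marginals and are calibrated", {
  cfg <- small_config(n_discovery = 1e5, seed = 12)
  pan <- simulate_reference_panel(cfg)
  cm <- simulate_causal_architecture(pan, cfg)
  ss <- simulate_discovery_sumstats(pan, cm, cfg, "standard")
  ana <- attr(ss, "analytic_beta_std")
  beta_std_obs <- ss$beta * sqrt(2 * ss$eaf * (1 - ss$eaf))
  fit <- lm(beta_std_obs ~ ana)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.05)

  # pure-null architecture: z^2 is chi-square(1) calibrated across seeds
  z2 <- unlist(lapply(1:10, function(s) {
    cfg0 <- small_config(n_causal = 0, seed = 100 + s)
    pan0 <- simulate_reference_panel(cfg0)
    cm0 <- simulate_causal_architecture(pan0, cfg0)
    ss0 <- simulate_discovery_sumstats(pan0, cm0, cfg0, "standard")
    (ss0$beta / ss0$se)^2
  }))
  expect_equal(mean(z2), 1, tolerance = 0.05)
})

test_that("family mode is unbiased with inflated standard errors", {
  cfg <- small_config(seed = 13, confound_strength = 0.5)
  pan <- simulate_reference_panel(cfg)
  cm <- simulate_causal_architecture(pan, cfg)
  std <- simulate_discovery_sumstats(pan, cm, cfg, "standard")
  fam <- simulate_discovery_sumstats(pan, cm, cfg, "family")
  expect_equal(fam$se / std$se, rep(1.6, nrow(std)), tolerance = 1e-12)
  # the confound shifts standard-mode betas away from the analytic values
  ana <- attr(std, "analytic_beta_std")
  sdall <- sqrt(2 * std$eaf * (1 - std$eaf))
  bias_std <- std$beta * sdall - ana
  bias_fam <- fam$beta * sdall - attr(fam, "analytic_beta_std")
  expect_gt(sd(bias_std), 3 * sd(bias_fam))
})

test_that("weight-table rules behave as specified", {
  ss <- data.frame(id = c("a", "b", "c"), effect_allele = "A",
                   other_allele = "G", eaf = 0.3,
                   beta = c(0.5, -0.2, 0.01), se = 0.1,
                   pval = c(1e-10, 0.2, 0.9), n = 1000L)
  expect_equal(derive_weight_table(ss, "identity")$weight, ss$beta)
  thr <- derive_weight_table(ss, "pvalue_threshold", p_cutoff = 5e-8)
  expect_equal(thr$weight, c(0.5, 0, 0))
  expect_equal(derive_weight_table(ss, "pvalue_threshold", p_cutoff = 1)$weight,
               ss$beta)
  # null simulation: genome-wide-significance threshold retains ~0 weights
  kept <- sapply(1:5, function(s) {
    cfg <- small_config(n_causal = 0, seed = 200 + s)
    pan <- simulate_reference_panel(cfg)
    cm <- simulate_causal_architecture(pan, cfg)
    ss0 <- simulate_discovery_sumstats(pan, cm, cfg, "standard")
    sum(derive_weight_table(ss0, "pvalue_threshold", 5e-8)$weight != 0)
  })
  expect_lt(mean(kept), 0.5)
})
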