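two_pop_fixture <- function(seed = 51, m = 60, n = 120) {
  p1 <- make_ld_panel(n = n, m = m, block = 4, seed = seed, flip_rate = 0.08)
  p2 <- make_ld_panel(n = n, m = m, block = 4, seed = seed + 1,
                      flip_rate = 0.25)
  list(p1 = p1, p2 = p2)
}

fake_ss <- function(panel, seed = 52) {
  set.seed(seed)
  m <- nrow(panel$variants)
  data.frame(id = panel$variants$id, effect_allele = "A", other_allele = "G",
             eaf = colMeans(panel$dosages, na.rm = TRUE) / 2,
             beta = rnorm(m, 0, 0.05), se = 0.01,
             pval = runif(m), n = 10000L, stringsAsFactors = FALSE)
}

test_that("clumping collapses perfect proxies and keeps independent variants", {
  # r2 threshold above the sampling noise floor so independence is clean
  pan <- make_random_panel(n = 400, m = 12, seed = 53)
  ss <- fake_ss(pan)
  ss$pval <- seq(0.01, 0.45, length.out = 12)
  cl <- clump(ss, pan, r2_min = 0.25)
  expect_setequal(cl$index_ids, pan$variants$id)         # no LD: all index
  expect_equal(top_snps(cl, 3), ss$id[order(ss$pval)][1:3])
  # duplicate column 1 kb away joins the lower-p variant's clump
  dup <- pan
  dup$dosages[, 2] <- dup$dosages[, 1]
  cl2 <- clump(ss, dup, r2_min = 0.25)
  expect_true("v001" %in% cl2$index_ids)
  expect_false("v002" %in% cl2$index_ids)
  expect_true("v002" %in% cl2$clumps[["v001"]])
  # p >= p_max variants are never indexed nor clumped
  ss$pval[5] <- 0.9
  cl3 <- clump(ss, pan, r2_min = 0.25)
  expect_false("v005" %in% unlist(cl3$clumps))
})

test_that("clump matches the exhaustive rescan oracle on random instances", {
  for (s in 1:3) {
    fx <- two_pop_fixture(seed = 60 + s, m = 48)
    ss <- fake_ss(fx$p1, seed = 70 + s)
    got <- clump(ss, fx$p1, window_kb = 5, r2_min = 0.1, p_max = 0.5)
    expect_identical(got$index_ids,
                     oracle_clump(ss, fx$p1, window_kb = 5, r2_min = 0.1,
                                  p_max = 0.5))
  }
  # 200-variant instance at production thresholds
  pan <- make_ld_panel(n = 80, m = 200, block = 5, seed = 80)
  ss <- fake_ss(pan, seed = 81)
  expect_identical(clump(ss, pan)$index_ids, oracle_clump(ss, pan))
})

test_that("common-SNP QC applies every filter and matches a per-filter oracle", {
  fx <- two_pop_fixture(seed = 90, m = 200, n = 150)
  p1 <- fx$p1; p2 <- fx$p2
  p2$dosages[, 3] <- 0                       # monomorphic in pop 2
  set.seed(91)
  p1$dosages[sample(150, 12), 5] <- NA       # call rate 92% in pop 1, but
                                             # each such sample only 0.5% missing
  qc <- qc_common_snps(list(p1, p2))
  expect_false("v003" %in% qc)
  expect_false("v005" %in% qc)
  oracle <- function(p) {
    keep <- p$samples[rowMeans(is.na(p$dosages)) < 0.01]
    pp <- subset_panel(p, samples = keep)
    ok <- character(0)
    for (j in seq_len(ncol(pp$dosages))) {
      x <- pp$dosages[, j]
      cr <- mean(!is.na(x)); fr <- mean(x, na.rm = TRUE) / 2
      g <- round(x[!is.na(x)])
      hw <- pgiport:::hwe_exact_p(sum(g == 1), sum(g == 2), sum(g == 0))
      if (cr > 0.95 && min(fr, 1 - fr) > 0.01 && hw > 1e-10)
        ok <- c(ok, pp$variants$id[j])
    }
    ok
  }
  expect_setequal(qc, intersect(oracle(p1), oracle(p2)))
})

test_that("candidate selection respects the window and r2 threshold exactly", {
  fx <- two_pop_fixture(seed = 100, m = 40)
  qc <- qc_common_snps(list(fx$p1, fx$p2))
  top <- qc[c(1, 5, 9)]
  got <- select_candidate_causal(top, fx$p1, qc, window_kb = 3, r2_min = 0.3)
  expect_identical(got, oracle_candidates(top, fx$p1, qc, window_kb = 3,
                                          r2_min = 0.3))
  # an index in the QC set is always its own candidate
  for (id in top) expect_true(id %in% got[[id]])
  # a candidate beyond the window is excluded regardless of correlation
  dup <- fx$p1
  dup$dosages[, 40] <- dup$dosages[, 1]      # perfect proxy 39 kb away
  got2 <- select_candidate_causal(fx$p1$variants$id[1], dup,
                                  fx$p1$variants$id, window_kb = 10)
  expect_false("v040" %in% got2[[1]])
})

test_that("LD summaries match a nested-loop oracle and the identity limits", {
  fx <- two_pop_fixture(seed = 110, m = 50)
  qc <- qc_common_snps(list(fx$p1, fx$p2))
  top <- qc[seq(1, length(qc), by = 4)][1:8]
  cand <- select_candidate_causal(top, fx$p1, qc, window_kb = 3, r2_min = 0.2)
  snps <- data.frame(id = top, beta_hat = seq(0.1, 0.8, length.out = 8))
  got <- ld_summaries(snps, cand, fx$p1, fx$p2, window_kb = 3)
  oracle <- oracle_ld_summaries(snps, cand, fx$p1, fx$p2, window_kb = 3)
  expect_equal(got$mean_r2_pop1, oracle$mean_r2_pop1, tolerance = 1e-10)
  expect_equal(got$mean_r1r2, oracle$mean_r1r2, tolerance = 1e-10)
  expect_equal(got$maf_pop1, oracle$maf_pop1, tolerance = 1e-12)
  # identical reference panels: r1 = r2 for every pair
  same <- ld_summaries(snps, cand, fx$p1, fx$p1, window_kb = 3)
  expect_equal(same$mean_r1r2, same$mean_r2_pop1, tolerance = 1e-12)
  # a SNP whose only candidate is itself
  solo <- ld_summaries(data.frame(id = top[1], beta_hat = 1),
                       stats::setNames(list(top[1]), top[1]),
                       fx$p1, fx$p2)
  expect_equal(solo$mean_r2_pop1, 1, tolerance = 1e-12)
  expect_equal(solo$mean_r1r2, 1, tolerance = 1e-12)
})

test_that("expected RA hits the identity limits and is symmetric-consistent", {
  sm <- data.frame(id = c("a", "b"), mean_r2_pop1 = c(0.8, 0.6),
                   mean_r1r2 = c(0.8, 0.6), maf_pop1 = c(0.2, 0.4),
                   maf_pop2 = c(0.2, 0.4), beta_hat = c(0.1, -0.2),
                   n_candidates = c(3L, 2L))
  e <- expected_ra(sm)
  expect_equal(e$factor_ld_maf, 1, tolerance = 1e-12)
  expect_equal(e$factor_varscale, 1, tolerance = 1e-12)
  expect_equal(e$ra_expected, 1, tolerance = 1e-12)
  # swapping population roles inverts the variance-scale factor
  sm2 <- sm; sm2$maf_pop2 <- c(0.1, 0.3)
  sw2 <- sm2; sw2$maf_pop1 <- sm2$maf_pop2; sw2$maf_pop2 <- sm2$maf_pop1
  expect_equal(expected_ra(sw2)$factor_varscale,
               1 / expected_ra(sm2)$factor_varscale, tolerance = 1e-12)
  # p(1-p) terms are invariant to which allele is labelled minor
  fl <- sm2; fl$maf_pop2 <- 1 - fl$maf_pop2
  expect_equal(expected_ra(fl)$ra_expected, expected_ra(sm2)$ra_expected,
               tolerance = 1e-12)
})

test_that("single-tag analytic oracle pins down the expected-RA bracketing", {
  # one tag SNP, one causal SNP; exact R^2 ratio from first principles over a
  # grid of LD and frequency configurations
  for (r1 in c(0.3, 0.6, 0.9)) for (r2 in c(0.3, 0.6, 0.9))
    for (p in c(0.1, 0.3, 0.5)) {
      pk1 <- 0.3; pk2 <- p      # tag frequencies
      pc1 <- 0.4; pc2 <- p      # causal frequencies
      sm <- data.frame(id = "tag", mean_r2_pop1 = r1^2, mean_r1r2 = r1 * r2,
                       maf_pop1 = pk1, maf_pop2 = pk2, beta_hat = 0.7,
                       n_candidates = 1L)
      h2_ratio <- (pc2 * (1 - pc2)) / (pc1 * (1 - pc1))  # equal causal betas
      e <- expected_ra(sm, effects_factor = h2_ratio)
      expect_equal(e$ra_expected, exact_one_tag_ra(r1, r2, pc1, pc2),
                   tolerance = 1e-8)
    }
})

test_that("stability curve is deterministic and flat for homogeneous blocks", {
  cfg <- small_config(seed = 120, n_samples_per_pop = 400)
  pan <- simulate_reference_panel(cfg)
  cm <- simulate_causal_architecture(pan, cfg)
  ss <- simulate_discovery_sumstats(pan, cm, cfg, "standard")
  p1 <- subset_panel(pan, samples = pan$ancestry == "POP1")
  p2 <- subset_panel(pan, samples = pan$ancestry == "POP2")
  sc <- suppressWarnings(stability_curve(ss, p1, p2, set_sizes = c(10, 40, 80)))
  sc2 <- suppressWarnings(stability_curve(ss, p1, p2, set_sizes = c(10, 40, 80)))
  expect_identical(sc, sc2)
  expect_equal(nrow(sc), 3)
  expect_equal(suppressWarnings(
    stability_curve(ss, p1, p2, set_sizes = 20))$snp_set_size, 20)
  # homogeneous architecture: the curve moves little across set sizes
  expect_lt(diff(range(sc$ra_expected[2:3])), 0.30)
})
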