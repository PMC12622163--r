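test_that("PCA ancestry model separates simulated populations and self-assigns", {
  cfg <- sim_config(n_variants = 400, n_blocks = 100, fst = 0.1,
                    n_samples_per_pop = 500, seed = 21)
  pan <- simulate_reference_panel(cfg)
  model <- fit_ancestry_model(pan, n_pcs = 10)
  sc <- pgiport:::project_panel(model, pan)
  # PC1 separates the two labels with zero overlap
  pc1 <- split(sc[, 1], pan$ancestry)
  expect_true(max(pc1$POP1) < min(pc1$POP2) || max(pc1$POP2) < min(pc1$POP1))
  lab <- assign_ancestry(model, pan)
  expect_gte(mean(lab == pan$ancestry), 0.99)
})

test_that("2-variant model loading equals the leading eigenvector", {
  pan <- make_random_panel(n = 200, m = 2, seed = 22)
  pan$ancestry <- rep(c("A", "B"), each = 100)
  model <- fit_ancestry_model(pan, n_pcs = 1)
  Z <- scale(pan$dosages)
  ev <- eigen(cor(pan$dosages))$vectors[, 1]
  expect_equal(abs(model$loadings[, 1]), abs(ev), tolerance = 1e-8)
})

test_that("assignment is invariant to the sign of PC loadings and flags outliers", {
  cfg <- small_config(fst = 0.1, n_samples_per_pop = 200, seed = 23)
  pan <- simulate_reference_panel(cfg)
  model <- fit_ancestry_model(pan, n_pcs = 5)
  flipped <- model
  flipped$loadings <- -model$loadings
  flipped$pc_mean <- -model$pc_mean
  expect_identical(as.vector(assign_ancestry(model, pan)),
                   as.vector(assign_ancestry(flipped, pan)))
  # a sample displaced 10+ SDs along PC1 from every ancestry is UNASSIGNED
  out <- pan
  shift <- 40 * model$scale * model$loadings[, 1]
  out$dosages[1, model$variant_ids] <-
    out$dosages[1, model$variant_ids] + shift
  expect_equal(unname(assign_ancestry(model, out)[1]), "UNASSIGNED")
})

test_that("ancestry model refuses undersized reference groups", {
  pan <- make_random_panel(n = 10, m = 20, seed = 24)
  pan$ancestry <- c(rep("A", 8), "B", "B")
  expect_error(fit_ancestry_model(pan), ">= 3 samples")
})

test_that("ld_prune retains independent variants and drops duplicates", {
  pan <- make_random_panel(n = 400, m = 20, seed = 25)
  expect_equal(ld_prune(pan, 1e6, 5, 0.1), pan$variants$id)
  dup <- pan
  dup$dosages[, 2] <- dup$dosages[, 1]
  kept <- ld_prune(dup, 1e6, 5, 0.1)
  expect_true("v001" %in% kept)
  expect_false("v002" %in% kept)
})

test_that("ld_prune matches the exhaustive windowed-greedy oracle", {
  for (s in 1:3) {
    pan <- make_ld_panel(n = 70, m = 40, block = 4, seed = 30 + s)
    expect_identical(ld_prune(pan, 5000, 3, 0.2),
                     oracle_prune(pan, 5000, 3, 0.2))
  }
  # 200-variant instance at the production parameters
  pan <- make_ld_panel(n = 60, m = 200, block = 5, seed = 40)
  expect_identical(ld_prune(pan, 1e6, 5, 0.1), oracle_prune(pan, 1e6, 5, 0.1))
})

test_that("GRM is VanRaden-normalized with unit diagonal for unrelated samples", {
  pan <- make_random_panel(n = 80, m = 600, seed = 26, maf = c(0.2, 0.5))
  G <- compute_grm(pan)
  expect_equal(mean(diag(G)), 1, tolerance = 0.05)
  offdiag <- G[upper.tri(G)]
  expect_lt(max(abs(offdiag)), 0.3)
})

test_that("relatedness filter removes exactly one of a duplicated sample", {
  # the GRM noise floor is ~1/sqrt(m); use a threshold well above it so only
  # the engineered duplicate pair trips the filter
  pan <- make_random_panel(n = 40, m = 300, seed = 27, maf = c(0.2, 0.5))
  pan$dosages[2, ] <- pan$dosages[1, ]     # make s002 a duplicate of s001
  pcs <- build_pc_controls(pan, n_pcs = 5, rel_threshold = 0.4)
  removed <- attr(pcs, "removed_related")
  expect_length(removed, 1)
  expect_true(removed %in% c("s001", "s002"))
  expect_equal(nrow(pcs), 40)              # relatives are projected back
  # without relatives nobody is removed
  pcs0 <- build_pc_controls(make_random_panel(n = 40, m = 300, seed = 28,
                                              maf = c(0.2, 0.5)),
                            n_pcs = 5, rel_threshold = 0.4)
  expect_length(attr(pcs0, "removed_related"), 0)
})

test_that("exact Hardy-Weinberg p-values match an enumeration oracle", {
  # direct enumeration of the Levene-Haldane distribution
  oracle <- function(het, hom1, hom2) {
    n <- het + hom1 + hom2
    nr <- 2 * min(hom1, hom2) + het
    hs <- seq(nr %% 2, min(nr, 2 * n - nr), by = 2)
    pr <- sapply(hs, function(h) {
      hr <- (nr - h) / 2; hc <- n - h - hr
      exp(lfactorial(n) - lfactorial(h) - lfactorial(hr) - lfactorial(hc) +
            h * log(2) + lfactorial(nr) + lfactorial(2 * n - nr) -
            lfactorial(2 * n))
    })
    sum(pr[pr <= pr[match(het, hs)] * (1 + 1e-12)])
  }
  for (g in list(c(12, 20, 18), c(2, 40, 8), c(25, 10, 15), c(0, 5, 45)))
    expect_equal(pgiport:::hwe_exact_p(g[1], g[2], g[3]),
                 oracle(g[1], g[2], g[3]), tolerance = 1e-10)
})

test_that("long-range-LD regions given in BED coordinates are excluded", {
  pan <- make_random_panel(n = 60, m = 30, seed = 29, maf = c(0.2, 0.5))
  # BED half-open [4999, 10000) covers 1-based positions 5000..10000
  reg <- data.frame(chrom = "1", start = 4999, end = 10000)
  pcs <- build_pc_controls(pan, long_range_ld_regions = reg, n_pcs = 3)
  used <- attr(pcs, "n_variants_used")
  expect_lte(used, 30 - 6)   # positions 5000..10000 hold 6 variants
})
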