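#' Simulation configuration for the two-population generator
#'
#' Defines the generating conditions for a pair of diverged populations with
#' block-wise local LD, a shared polygenic architecture, and a discovery GWAS
#' in population 1. Population divergence follows the Balding-Nichols model
#' (beta-distributed per-population allele frequencies around an ancestral
#' frequency, parameterized by `fst`); local LD comes from a first-order
#' Gaussian-copula Markov process along each block of adjacent variants.
#'
#' Defaults describe a realistic reference/target contrast: `fst = 0.15`
#' (about the magnitude of European-African divergence), a 1% ancestral MAF
#' floor matching the common-SNP filters used downstream, polygenic trait
#' architecture (`n_causal = 200`, `h2 = 0.5` in both populations), perfectly
#' shared causal effects (`rho_b = 1`) and a large analytic discovery GWAS
#' (`n_discovery = 1e5`).
#'
#' @param n_variants total number of variants.
#' @param n_blocks number of independent LD blocks (variants are split evenly).
#' @param block_ld_rho latent adjacent-variant correlation within a block,
#'   in `[0, 1)`; a scalar, or a length-2 vector giving each population its
#'   own LD strength (the default `c(0.95, 0.65)` mirrors the shorter-range
#'   LD of African-ancestry populations relative to a European-like
#'   reference).
#' @param fst Balding-Nichols divergence parameter, in `[0, 0.5]`.
#' @param n_samples_per_pop diploid samples simulated per population.
#' @param n_causal number of causal variants.
#' @param causal_clustering `"block"` (default): whole LD blocks are drawn
#'   uniformly without replacement and all their variants are causal, a
#'   dense local architecture under which every strong-LD neighbour of a
#'   sentinel SNP is a causal candidate; `"uniform"`: causal variants are
#'   drawn uniformly without replacement genome-wide.
#' @param rho_b cross-population correlation of causal effects, in `[-1, 1]`.
#' @param h2_pop1,h2_pop2 SNP heritability of the trait in each population.
#' @param n_discovery discovery GWAS sample size (emulated analytically).
#' @param confound_strength stratification confounding added to
#'   standard-mode discovery betas and to the population-1 phenotype.
#' @param family_se_inflation SE inflation factor for family-based ("fGWAS")
#'   summary statistics, emulating their smaller effective sample size.
#' @param maf_floor lower bound of the ancestral allele-frequency draw.
#' @param within_block_fst small per-SNP Balding-Nichols jitter around the
#'   block-level population frequency (default 0.01). Divergence acts at
#'   the block level so that linked variants share drift history, as
#'   variants on a real haplotype do; without this, linked variants would
#'   have independent frequencies and realistic within-block r-squared
#'   values would be unattainable.
#' @param block_spacing_bp base pairs between block start positions.
#' @param within_block_spacing_bp base pairs between adjacent variants
#'   inside a block.
#' @param seed integer seed; every generator operation is deterministic
#'   given the config.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_variants = 5000, n_blocks = 1250,
                       block_ld_rho = c(0.95, 0.65),
                       fst = 0.15, n_samples_per_pop = 2000, n_causal = 200,
                       rho_b = 1, h2_pop1 = 0.5, h2_pop2 = 0.5,
                       causal_clustering = c("block", "uniform"),
                       n_discovery = 1e5, confound_strength = 0,
                       family_se_inflation = 1.6, maf_floor = 0.01,
                       within_block_fst = 0.01,
                       block_spacing_bp = 1e6, within_block_spacing_bp = 5000,
                       seed = 1) {
  causal_clustering <- match.arg(causal_clustering)
  if (length(block_ld_rho) == 1) block_ld_rho <- rep(block_ld_rho, 2)
  stopifnot(n_variants >= 1, n_blocks >= 1, n_blocks <= n_variants,
            length(block_ld_rho) == 2,
            all(block_ld_rho >= 0), all(block_ld_rho < 1),
            fst >= 0, fst <= 0.5,
            n_samples_per_pop >= 2,
            n_causal >= 0, n_causal <= n_variants,
            rho_b >= -1, rho_b <= 1,
            h2_pop1 >= 0, h2_pop1 <= 1, h2_pop2 >= 0, h2_pop2 <= 1,
            n_discovery >= 1, confound_strength >= 0,
            family_se_inflation >= 1,
            maf_floor > 0, maf_floor < 0.5,
            within_block_fst >= 0, within_block_fst < 0.5)
  structure(list(n_variants = as.integer(n_variants),
                 n_blocks = as.integer(n_blocks),
                 block_ld_rho = block_ld_rho, fst = fst,
                 n_samples_per_pop = as.integer(n_samples_per_pop),
                 n_causal = as.integer(n_causal),
                 causal_clustering = causal_clustering, rho_b = rho_b,
                 h2_pop1 = h2_pop1, h2_pop2 = h2_pop2,
                 n_discovery = n_discovery,
                 confound_strength = confound_strength,
                 family_se_inflation = family_se_inflation,
                 maf_floor = maf_floor,
                 within_block_fst = within_block_fst,
                 block_spacing_bp = block_spacing_bp,
                 within_block_spacing_bp = within_block_spacing_bp,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic sub-seeds so each operation is reproducible standalone
sim_seed <- function(config, offset) (config$seed * 97L + offset) %% .Machine$integer.max

block_index <- function(config) {
  sort(rep_len(seq_len(config$n_blocks), config$n_variants))
}

variant_positions <- function(config) {
  blk <- block_index(config)
  within <- stats::ave(seq_along(blk), blk, FUN = seq_along)
  as.integer((blk - 1) * config$block_spacing_bp + 1 +
               (within - 1) * config$within_block_spacing_bp)
}

# haplotypes for one population: latent AR(1) per block, thresholded at the
# population allele frequency (Gaussian copula)
sim_haplotypes <- function(n_hap, freqs, blk, rho) {
  m <- length(freqs)
  z <- matrix(stats::rnorm(n_hap * m), n_hap, m)
  if (rho > 0 && m > 1) {
    s <- sqrt(1 - rho^2)
    for (j in 2:m) {
      if (blk[j] == blk[j - 1])
        z[, j] <- rho * z[, j - 1] + s * z[, j]
    }
  }
  thr <- stats::qnorm(freqs)
  (z < matrix(thr, n_hap, m, byrow = TRUE)) + 0
}

#' Simulate a two-population reference panel
#'
#' Ancestral allele frequencies are uniform on `[maf_floor, 1 - maf_floor]`,
#' one per LD block; per-population block frequencies follow the
#' Balding-Nichols beta distribution with parameter `fst`, and each variant
#' receives an additional small Balding-Nichols jitter (`within_block_fst`)
#' around its population block frequency, so that linked variants share
#' their drift history. Haplotypes are generated by a first-order Markov
#' (Gaussian-copula) process with adjacent latent correlation `block_ld_rho`
#' within blocks (population-specific), independent across blocks; diploid
#' dosages are the sum of two haplotypes. Populations are labelled `"POP1"`
#' and `"POP2"`.
#'
#' @param config a [sim_config()].
#' @return a [genotype_panel()] with ancestry labels, carrying the realized
#'   per-population frequencies in attribute `"pop_freqs"`.
#' @export
simulate_reference_panel <- function(config) {
  set.seed(sim_seed(config, 1L))
  m <- config$n_variants
  blk <- block_index(config)
  bn_draw <- function(p, f) {
    if (f <= 0) return(p)
    pmin(pmax(stats::rbeta(length(p), p * (1 - f) / f,
                           (1 - p) * (1 - f) / f), 1e-4), 1 - 1e-4)
  }
  p_anc_blk <- stats::runif(config$n_blocks, config$maf_floor,
                            1 - config$maf_floor)
  p_anc <- p_anc_blk[blk]
  p1 <- bn_draw(bn_draw(p_anc_blk, config$fst)[blk], config$within_block_fst)
  p2 <- bn_draw(bn_draw(p_anc_blk, config$fst)[blk], config$within_block_fst)
  n <- config$n_samples_per_pop
  d1 <- sim_haplotypes(n, p1, blk, config$block_ld_rho[1]) +
    sim_haplotypes(n, p1, blk, config$block_ld_rho[1])
  d2 <- sim_haplotypes(n, p2, blk, config$block_ld_rho[2]) +
    sim_haplotypes(n, p2, blk, config$block_ld_rho[2])
  variants <- data.frame(id = sprintf("snp%05d", seq_len(m)),
                         chrom = "1", pos = variant_positions(config),
                         a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  panel <- genotype_panel(rbind(d1, d2), variants,
                          samples = c(sprintf("P1_%04d", seq_len(n)),
                                      sprintf("P2_%04d", seq_len(n))),
                          ancestry = rep(c("POP1", "POP2"), each = n))
  attr(panel, "pop_freqs") <- data.frame(id = variants$id, p_anc = p_anc,
                                         p_pop1 = p1, p_pop2 = p2)
  if (config$fst == 0)
    message("fst = 0: populations are exchangeable; PCA separation is not expected")
  panel
}

#' Simulate a polygenic causal architecture
#'
#' Under `causal_clustering = "block"` (the default) whole LD blocks are
#' sampled uniformly without replacement and every variant in a sampled
#' block is causal; under `"uniform"` individual variants are sampled
#' uniformly without replacement. Standardized effects
#' `(beta_pop1, beta_pop2)` are bivariate normal with correlation `rho_b`,
#' then rescaled within each population so the realized genetic variance
#' (over that population's panel samples) equals the target heritability
#' when unit-total phenotype noise is added.
#'
#' @param panel a two-population panel from [simulate_reference_panel()].
#' @param config the [sim_config()] used to build it.
#' @return an object of class `causal_model`: `causal_ids`, standardized
#'   per-population effects `beta_pop1`/`beta_pop2`, and the per-population
#'   genetic score for every panel sample.
#' @export
simulate_causal_architecture <- function(panel, config) {
  if (nrow(panel$variants) < config$n_causal)
    stop("panel has fewer variants than n_causal")
  set.seed(sim_seed(config, 2L))
  m <- nrow(panel$variants)
  k <- config$n_causal
  if (identical(config$causal_clustering, "block")) {
    blk <- block_index(config)
    bsize <- tabulate(blk)
    nb <- which(cumsum(sort(bsize, decreasing = TRUE)) >= k)[1]
    pick <- sample.int(config$n_blocks, nb)
    causal_idx <- sort(which(blk %in% pick))
    if (length(causal_idx) > k) causal_idx <- causal_idx[seq_len(k)]
    k <- length(causal_idx)
  } else {
    causal_idx <- sort(sample.int(m, k))
  }
  b1 <- stats::rnorm(k)
  b2 <- config$rho_b * b1 + sqrt(1 - config$rho_b^2) * stats::rnorm(k)
  pops <- c("POP1", "POP2")
  score <- numeric(length(panel$samples))
  betas <- list(b1, b2)
  h2 <- c(config$h2_pop1, config$h2_pop2)
  out_betas <- vector("list", 2)
  for (i in 1:2) {
    rows <- panel$ancestry == pops[i]
    X <- panel$dosages[rows, causal_idx, drop = FALSE]
    X[is.na(X)] <- 0
    Xs <- standardize_columns(X)
    g <- drop(Xs %*% betas[[i]])
    vg <- stats::var(g)
    sc <- if (h2[i] > 0 && vg > 0) sqrt(h2[i] / vg) else 0
    out_betas[[i]] <- betas[[i]] * sc
    score[rows] <- g * sc
  }
  structure(list(causal_ids = panel$variants$id[causal_idx],
                 causal_idx = causal_idx,
                 beta_pop1 = out_betas[[1]], beta_pop2 = out_betas[[2]],
                 raw_beta_pop1 = b1, raw_beta_pop2 = b2,
                 genetic_score = score),
            class = "causal_model")
}

# column standardization with a zero-variance guard
standardize_columns <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  v <- (colSums(X * X) - n * mu^2) / (n - 1)
  sd <- sqrt(pmax(v, 0))
  sd[sd < 1e-12] <- 1
  X <- X - rep(mu, each = n)
  X / rep(sd, each = n)
}

# within-population-1 stratification gradient: the standardized projection of
# standardized genotypes onto the cross-population frequency-difference axis
stratification_gradient <- function(panel, config) {
  fr <- attr(panel, "pop_freqs")
  w <- fr$p_pop1 - fr$p_pop2
  if (all(w == 0)) w <- rep(1, length(w))
  X <- panel$dosages
  X[is.na(X)] <- 0
  u <- drop(standardize_columns(X) %*% w)
  # center/scale within population 1 so the gradient is a unit-variance
  # within-reference-population axis
  p1 <- panel$ancestry == "POP1"
  (u - mean(u[p1])) / stats::sd(u[p1])
}

#' Simulate phenotypes for the panel samples
#'
#' `y = genetic score + confounder + N(0, 1 - h2)` per population, with the
#' genetic score from [simulate_causal_architecture()]. The optional
#' stratification confounder (`confound_strength > 0`) adds
#' `confound_strength x` the population-1 frequency-gradient score to the
#' population-1 phenotype only, emulating an environmental gradient aligned
#' with ancestry structure in the discovery/reference population. Optional
#' demographic effects and a second wave support residualization tests.
#'
#' @param panel a two-population panel.
#' @param causal a `causal_model`.
#' @param config the [sim_config()].
#' @param phenotype phenotype name for the output table.
#' @param n_waves number of measurement waves (default 1).
#' @param sex_effect,age_effect additive covariate effects (default 0).
#' @return a phenotype table: `sample_id`, `phenotype`, `value`, `wave`,
#'   `sex`, `birth_year`, `age`.
#' @export
simulate_phenotypes <- function(panel, causal, config, phenotype = "trait",
                                n_waves = 1, sex_effect = 0, age_effect = 0) {
  set.seed(sim_seed(config, 3L))
  n <- length(panel$samples)
  h2 <- ifelse(panel$ancestry == "POP1", config$h2_pop1, config$h2_pop2)
  g <- causal$genetic_score
  conf <- 0
  if (config$confound_strength > 0) {
    u <- stratification_gradient(panel, config)
    conf <- ifelse(panel$ancestry == "POP1", config$confound_strength * u, 0)
  }
  sex <- stats::rbinom(n, 1, 0.5)
  birth_year <- sample(1940:1970, n, replace = TRUE)
  out <- vector("list", n_waves)
  for (w in seq_len(n_waves)) {
    age <- 2010 - birth_year + (w - 1) * 4 + stats::runif(n, -0.5, 0.5)
    e <- stats::rnorm(n, 0, sqrt(pmax(1 - h2, 0)))
    y <- g + conf + e + sex_effect * sex + age_effect * (age - mean(age)) / 10
    out[[w]] <- data.frame(sample_id = panel$samples, phenotype = phenotype,
                           value = y, wave = w, sex = sex,
                           birth_year = birth_year, age = age,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate discovery GWAS summary statistics in population 1
#'
#' Marginal effects are computed analytically from the population-1 panel LD:
#' the standardized marginal effect of variant `j` is the sum over causal
#' variants of `r(j, c) x beta_c`, to which Gaussian estimation noise with
#' standard error `1/sqrt(2 p (1-p) n_discovery)` (per-allele scale) is added.
#' `mode = "standard"` additionally biases every beta along the population-1
#' stratification gradient in proportion to `confound_strength`;
#' `mode = "family"` is unbiased but inflates the SE by
#' `family_se_inflation`, emulating the smaller effective sample size of
#' within-family designs.
#'
#' @param panel a two-population panel.
#' @param causal a `causal_model`.
#' @param config the [sim_config()].
#' @param mode `"standard"` or `"family"`.
#' @return a summary-statistics data.frame: `id`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, `n` (per-allele scale,
#'   standardized phenotype), with the noiseless, unconfounded standardized marginal
#'   betas in attribute `"analytic_beta_std"`.
#' @export
simulate_discovery_sumstats <- function(panel, causal, config,
                                        mode = c("standard", "family")) {
  mode <- match.arg(mode)
  if (config$n_discovery < 100)
    warning("n_discovery < 100: normal-approximation summary statistics unreliable")
  set.seed(sim_seed(config, if (mode == "standard") 4L else 5L))
  rows <- panel$ancestry == "POP1"
  X <- panel$dosages[rows, , drop = FALSE]
  X[is.na(X)] <- 0
  n1 <- nrow(X)
  Xs <- standardize_columns(X)
  # population LD is block-diagonal by construction, so the infinite-sample
  # marginal effect of a variant only involves causal variants in its own
  # block; estimate those within-block correlations from the panel
  beta_std <- numeric(ncol(X))
  if (config$n_causal > 0) {
    blk <- block_index(config)
    for (b in unique(blk[causal$causal_idx])) {
      jb <- which(blk == b)
      cb <- causal$causal_idx[blk[causal$causal_idx] == b]
      bb <- causal$beta_pop1[match(cb, causal$causal_idx)]
      beta_std[jb] <- drop(crossprod(Xs[, jb, drop = FALSE],
                                     Xs[, cb, drop = FALSE] %*% bb)) / (n1 - 1)
    }
  }
  bias_std <- 0
  if (mode == "standard" && config$confound_strength > 0) {
    u <- stratification_gradient(panel, config)[rows]
    bias_std <- config$confound_strength *
      drop(crossprod(Xs, (u - mean(u)) / stats::sd(u))) / (n1 - 1)
  }
  p1 <- colMeans(X) / 2
  sd_allele <- sqrt(2 * p1 * (1 - p1))
  sd_allele[sd_allele == 0] <- NA
  se_std <- 1 / sqrt(config$n_discovery)
  if (mode == "family") se_std <- se_std * config$family_se_inflation
  obs_std <- beta_std + bias_std + stats::rnorm(length(beta_std), 0, se_std)
  beta <- obs_std / sd_allele
  se <- se_std / sd_allele
  z <- obs_std / se_std
  ss <- data.frame(id = panel$variants$id,
                   effect_allele = panel$variants$a1,
                   other_allele = panel$variants$a2,
                   eaf = p1, beta = beta, se = se,
                   pval = pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin),
                   n = as.integer(config$n_discovery),
                   stringsAsFactors = FALSE)
  keep <- !is.na(ss$beta)
  ss <- ss[keep, , drop = FALSE]
  rownames(ss) <- NULL
  attr(ss, "analytic_beta_std") <- beta_std[keep]   # aligned with rows
  ss
}

#' Derive a PGI weight table from summary statistics
#'
#' @param sumstats a summary-statistics data.frame.
#' @param rule `"identity"` (weights are the betas) or `"pvalue_threshold"`
#'   (weights with `pval` above `p_cutoff` are zeroed).
#' @param p_cutoff p-value cutoff for the threshold rule (default `5e-8`).
#' @return a weight table: `id`, `effect_allele`, `other_allele`, `weight`.
#' @export
derive_weight_table <- function(sumstats, rule = c("identity", "pvalue_threshold"),
                                p_cutoff = 5e-8) {
  rule <- match.arg(rule)
  if (nrow(sumstats) == 0) stop("empty summary statistics")
  w <- sumstats$beta
  if (rule == "pvalue_threshold") w[sumstats$pval > p_cutoff] <- 0
  data.frame(id = sumstats$id, effect_allele = sumstats$effect_allele,
             other_allele = sumstats$other_allele, weight = w,
             stringsAsFactors = FALSE)
}
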