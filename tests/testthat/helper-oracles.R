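# Brute-force oracles and small fixture builders. Oracles are written as
# direct transcriptions of the definitions (nested loops, rescans) and stay
# independent of the package's vectorized implementations.

make_random_panel <- function(n = 60, m = 30, seed = 1, n_chrom = 1,
                              maf = c(0.1, 0.5), missing_rate = 0) {
  set.seed(seed)
  p <- runif(m, maf[1], maf[2])
  dos <- sapply(p, function(pp) rbinom(n, 2, pp))
  if (missing_rate > 0)
    dos[matrix(runif(n * m) < missing_rate, n, m)] <- NA
  chrom <- as.character(rep_len(seq_len(n_chrom), m))
  pos <- unlist(lapply(split(seq_len(m), chrom), seq_along))
  pos <- integer(m)
  for (cc in unique(chrom)) pos[chrom == cc] <- seq_len(sum(chrom == cc)) * 1000L
  genotype_panel(dos,
                 data.frame(id = sprintf("v%03d", seq_len(m)), chrom = chrom,
                            pos = pos, a1 = "A", a2 = "G",
                            stringsAsFactors = FALSE),
                 samples = sprintf("s%03d", seq_len(n)))
}

# correlated-column panel: blocks of near-duplicate variants
make_ld_panel <- function(n = 80, m = 40, block = 4, seed = 2, flip_rate = 0.1) {
  set.seed(seed)
  base <- sapply(runif(ceiling(m / block), 0.2, 0.8),
                 function(pp) rbinom(n, 2, pp))
  dos <- matrix(0, n, m)
  for (j in seq_len(m)) {
    src <- base[, ceiling(j / block)]
    noise <- rbinom(n, 1, flip_rate)
    dos[, j] <- pmin(pmax(src + noise * sample(c(-1, 1), n, TRUE), 0), 2)
  }
  genotype_panel(dos,
                 data.frame(id = sprintf("v%03d", seq_len(m)), chrom = "1",
                            pos = seq_len(m) * 1000L, a1 = "A", a2 = "G",
                            stringsAsFactors = FALSE),
                 samples = sprintf("s%03d", seq_len(n)))
}

imputed_std <- function(panel) {
  X <- panel$dosages
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    X[, j] <- x
  }
  mu <- colMeans(X); sdv <- apply(X, 2, sd); sdv[sdv == 0] <- 1
  sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
}

pair_r <- function(panel, i, j) {
  Z <- imputed_std(panel)
  sum(Z[, i] * Z[, j]) / (nrow(Z) - 1)
}

oracle_prune <- function(panel, window_bp, step_variants, r2_max) {
  Z <- imputed_std(panel)
  n <- nrow(Z); m <- ncol(Z); pos <- panel$variants$pos
  keep <- rep(TRUE, m)
  start <- 1
  while (start <= m) {
    win <- which(pos >= pos[start] & pos - pos[start] <= window_bp &
                   seq_len(m) >= start)
    for (j in win) {
      if (!keep[j]) next
      for (i in win[win < j]) {
        if (!keep[i]) next
        r <- sum(Z[, i] * Z[, j]) / (n - 1)
        if (r^2 > r2_max) { keep[j] <- FALSE; break }
      }
    }
    start <- start + step_variants
  }
  panel$variants$id[keep]
}

# exhaustive greedy clump: rescan every remaining variant each round
oracle_clump <- function(ss, panel, window_kb = 2000, r2_min = 0.01,
                         p_max = 0.5) {
  Z <- imputed_std(panel)
  n <- nrow(Z)
  v <- panel$variants
  ord <- order(ss$pval, ss$id)
  ss <- ss[ord, , drop = FALSE]
  unassigned <- rep(TRUE, nrow(ss))
  index_ids <- character(0)
  repeat {
    cand <- which(unassigned & ss$pval < p_max)
    if (length(cand) == 0) break
    i <- cand[1]
    unassigned[i] <- FALSE
    index_ids <- c(index_ids, ss$id[i])
    vi <- match(ss$id[i], v$id)
    for (j in which(unassigned)) {
      if (ss$pval[j] >= p_max) next
      vj <- match(ss$id[j], v$id)
      if (v$chrom[vj] != v$chrom[vi]) next
      if (abs(v$pos[vj] - v$pos[vi]) > window_kb * 1000) next
      r <- sum(Z[, vi] * Z[, vj]) / (n - 1)
      if (r^2 > r2_min) unassigned[j] <- FALSE
    }
  }
  index_ids
}

oracle_candidates <- function(top_ids, panel, qc_ids, window_kb = 100,
                              r2_min = 0.45) {
  v <- panel$variants
  out <- list()
  for (id in top_ids) {
    vi <- match(id, v$id)
    hits <- character(0)
    for (q in qc_ids) {
      qi <- match(q, v$id)
      if (v$chrom[qi] != v$chrom[vi]) next
      if (abs(v$pos[qi] - v$pos[vi]) > window_kb * 1000) next
      if (pair_r(panel, vi, qi)^2 > r2_min) hits <- c(hits, q)
    }
    out[[id]] <- hits
  }
  out
}

oracle_ld_summaries <- function(pgi_snps, candidates, p1, p2,
                                window_kb = 100) {
  rows <- list()
  for (k in seq_len(nrow(pgi_snps))) {
    id <- pgi_snps$id[k]
    cand <- candidates[[id]]
    v <- p1$variants
    vi <- match(id, v$id)
    cand <- cand[abs(v$pos[match(cand, v$id)] - v$pos[vi]) <= window_kb * 1000]
    if (length(cand) == 0) next
    r1 <- r2 <- numeric(length(cand))
    for (ci in seq_along(cand)) {
      r1[ci] <- pair_r(p1, vi, match(cand[ci], p1$variants$id))
      r2[ci] <- pair_r(p2, match(id, p2$variants$id),
                       match(cand[ci], p2$variants$id))
    }
    f1 <- mean(p1$dosages[, vi], na.rm = TRUE) / 2
    f2 <- mean(p2$dosages[, match(id, p2$variants$id)], na.rm = TRUE) / 2
    rows[[id]] <- data.frame(id = id, mean_r2_pop1 = mean(r1^2),
                             mean_r1r2 = mean(r1 * r2),
                             maf_pop1 = min(f1, 1 - f1),
                             maf_pop2 = min(f2, 1 - f2),
                             beta_hat = pgi_snps$beta_hat[k],
                             n_candidates = length(cand))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

oracle_pgi <- function(panel, weights) {
  raw <- numeric(length(panel$samples))
  for (s in seq_along(panel$samples)) {
    acc <- 0
    for (k in seq_len(nrow(weights))) {
      j <- match(weights$id[k], panel$variants$id)
      if (is.na(j)) next
      d <- panel$dosages[s, j]
      if (is.na(d)) d <- mean(panel$dosages[, j], na.rm = TRUE)
      acc <- acc + weights$weight[k] * d
    }
    raw[s] <- acc
  }
  raw
}

hudson_fst <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# exact out-of-sample R^2 ratio of a one-tag/one-causal predictor, from first
# principles: R^2_i = cor(tag, y_i)^2 = beta^2 r_i^2 2 p_c,i q_c,i / var(y_i)
exact_one_tag_ra <- function(r1, r2, pc1, pc2, beta = 0.3,
                             var_y1 = 1, var_y2 = 1) {
  r2_1 <- beta^2 * r1^2 * 2 * pc1 * (1 - pc1) / var_y1
  r2_2 <- beta^2 * r2^2 * 2 * pc2 * (1 - pc2) / var_y2
  r2_2 / r2_1
}

small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_variants = 400, n_blocks = 100, n_samples_per_pop = 300,
                   n_causal = 40, seed = 1)
  do.call(sim_config, utils::modifyList(defaults, args))
}
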