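# internal: standardized, mean-imputed dosage matrix plus allele frequencies
std_dosage <- function(panel, hard_calls = FALSE) {
  X <- panel$dosages
  if (hard_calls) X <- round(X)
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mu[j]
  }
  list(Z = standardize_columns(X), freq = colMeans(X) / 2, n = nrow(X))
}

#' Greedy p-value-ordered LD clumping
#'
#' The lowest-p unassigned variant becomes an index SNP; every unassigned
#' variant within `window_kb` of it with `r^2 > r2_min` to it (in the
#' reference panel) and `p < p_max` joins its clump; the procedure repeats
#' until no unassigned variant with `p < p_max` remains. Ties in p are
#' broken by variant id.
#'
#' @param sumstats summary statistics (`id`, `pval`, ...); variants must be
#'   present in the reference.
#' @param reference a `genotype_panel` used for LD (position-sorted).
#' @param window_kb clump window half-width in kb (default 2000).
#' @param r2_min correlation threshold for clump membership (default 0.01).
#' @param p_max maximum p-value considered (default 0.5).
#' @return object of class `top_snp_set`: `index_ids` (ordered by ascending
#'   p), `index_pval`, and `clumps` (named list of member ids per index).
#' @export
clump <- function(sumstats, reference, window_kb = 2000, r2_min = 0.01,
                  p_max = 0.5) {
  idx <- match(sumstats$id, reference$variants$id)
  if (anyNA(idx))
    stop("summary-statistics variant(s) absent from the reference panel: ",
         paste(utils::head(sumstats$id[is.na(idx)], 3), collapse = ", "))
  ord <- order(idx)
  ss <- sumstats[ord, , drop = FALSE]
  vidx <- idx[ord]
  pos <- reference$variants$pos[vidx]
  if (is.unsorted(pos)) stop("reference variants must be position-sorted")
  chrom <- reference$variants$chrom[vidx]
  sd <- std_dosage(subset_panel(reference, variants = vidx))
  Z <- sd$Z; n <- sd$n
  m <- nrow(ss)
  assigned <- rep(FALSE, m)
  eligible <- ss$pval < p_max
  # processing order: ascending p, ties by id
  proc <- order(ss$pval, ss$id)
  index_ids <- character(0); index_p <- numeric(0); clumps <- list()
  w <- window_kb * 1000
  for (i in proc) {
    if (assigned[i] || !eligible[i]) next
    assigned[i] <- TRUE
    win <- which(chrom == chrom[i] & abs(pos - pos[i]) <= w &
                   !assigned & eligible)
    members <- ss$id[i]
    if (length(win) > 0) {
      r <- drop(crossprod(Z[, win, drop = FALSE], Z[, i])) / (n - 1)
      hit <- win[r^2 > r2_min]
      if (length(hit) > 0) {
        assigned[hit] <- TRUE
        members <- c(members, ss$id[hit])
      }
    }
    index_ids <- c(index_ids, ss$id[i])
    index_p <- c(index_p, ss$pval[i])
    clumps[[ss$id[i]]] <- members
  }
  structure(list(index_ids = index_ids, index_pval = index_p, clumps = clumps),
            class = "top_snp_set")
}

#' @export
print.top_snp_set <- function(x, ...) {
  cat("top_snp_set:", length(x$index_ids), "index SNPs,",
      sum(lengths(x$clumps)), "clumped variants\n")
  invisible(x)
}

#' Extract the top-K index SNPs of a clumped set
#'
#' @param set a `top_snp_set`.
#' @param size requested number of index SNPs.
#' @return character vector of index ids (ascending p), with a warning when
#'   fewer than `size` index SNPs exist.
#' @export
top_snps <- function(set, size) {
  if (length(set$index_ids) < size)
    warning("only ", length(set$index_ids), " index SNPs available (",
            size, " requested)")
  utils::head(set$index_ids, size)
}

#' Common-SNP quality control across populations
#'
#' Within each population: samples with missingness >= 1% are dropped first;
#' variants are then required to pass call rate > 95%, MAF > 1% and an exact
#' Hardy-Weinberg test at `p > 1e-10`. The returned set is the intersection
#' of passing variants over all populations.
#'
#' @param panels list of `genotype_panel`, one per population.
#' @return character vector of shared QC-passing variant ids.
#' @export
qc_common_snps <- function(panels) {
  if (length(panels) < 2) stop("need at least two population panels")
  pass <- lapply(panels, function(p) {
    smiss <- rowMeans(is.na(p$dosages))
    p <- subset_panel(p, samples = which(smiss < 0.01))
    X <- p$dosages
    call_rate <- colMeans(!is.na(X))
    fr <- colMeans(X, na.rm = TRUE) / 2
    maf <- pmin(fr, 1 - fr)
    hwe <- hwe_pvalues(p)
    p$variants$id[call_rate > 0.95 & maf > 0.01 & hwe > 1e-10]
  })
  out <- Reduce(intersect, pass)
  if (length(out) == 0)
    stop("no variant passes QC in every population")
  out
}

#' Select candidate causal SNPs around index SNPs
#'
#' For each index SNP, candidates are the QC-passing variants within
#' `window_kb` whose squared correlation with the index exceeds `r2_min` in
#' the designated (discovery-ancestry) reference panel. An index SNP that is
#' itself in the QC set is always its own candidate (`r^2 = 1`).
#'
#' @param top_ids character vector of index SNP ids.
#' @param reference_pop1 discovery-ancestry `genotype_panel`.
#' @param qc_ids QC-passing variant ids (from [qc_common_snps()]).
#' @param window_kb window half-width in kb (default 100).
#' @param r2_min candidate r-squared threshold (default 0.45).
#' @return named list: for each index id, a character vector of candidate
#'   ids (possibly empty).
#' @export
select_candidate_causal <- function(top_ids, reference_pop1, qc_ids,
                                    window_kb = 100, r2_min = 0.45) {
  v <- reference_pop1$variants
  qpos <- match(qc_ids, v$id)
  if (anyNA(qpos)) stop("QC id(s) absent from the reference panel")
  sd <- std_dosage(subset_panel(reference_pop1, variants = qpos))
  Z <- sd$Z; n <- sd$n
  qc_chrom <- v$chrom[qpos]; qc_bp <- v$pos[qpos]
  w <- window_kb * 1000
  out <- vector("list", length(top_ids)); names(out) <- top_ids
  for (k in seq_along(top_ids)) {
    vi <- match(top_ids[k], v$id)
    if (is.na(vi)) stop("index SNP absent from the reference panel: ", top_ids[k])
    win <- which(qc_chrom == v$chrom[vi] & abs(qc_bp - v$pos[vi]) <= w)
    if (length(win) == 0) { out[[k]] <- character(0); next }
    gi <- reference_pop1$dosages[, vi]
    gi[is.na(gi)] <- mean(gi, na.rm = TRUE)
    s <- stats::sd(gi)
    if (s == 0) { out[[k]] <- character(0); next }
    zi <- (gi - mean(gi)) / s
    r <- drop(crossprod(Z[, win, drop = FALSE], zi)) / (n - 1)
    out[[k]] <- qc_ids[win][r^2 > r2_min]
  }
  out
}

#' Cross-population LD and MAF summaries for PGI-SNPs
#'
#' For each PGI-SNP `k` and its candidate causal SNPs within `window_kb`:
#' the mean squared allele-count correlation with the candidates in
#' population 1, the mean product of the population-1 and population-2
#' correlations (under a shared allele coding), and the per-population minor
#' allele frequencies of `k`. PGI-SNPs with no in-window candidate are
#' excluded and counted.
#'
#' @param pgi_snps data.frame `id`, `beta_hat` (discovery marginal effect).
#' @param candidates named list from [select_candidate_causal()].
#' @param ref_pop1,ref_pop2 reference panels with consistent allele coding.
#' @param window_kb window half-width in kb (default 100).
#' @param hard_calls round dosages to hard calls before correlating.
#' @return data.frame of class `ld_summary`: `id`, `mean_r2_pop1`,
#'   `mean_r1r2`, `maf_pop1`, `maf_pop2`, `beta_hat`, `n_candidates`;
#'   attribute `n_excluded` counts PGI-SNPs without candidates.
#' @export
ld_summaries <- function(pgi_snps, candidates, ref_pop1, ref_pop2,
                         window_kb = 100, hard_calls = FALSE) {
  stopifnot(all(c("id", "beta_hat") %in% names(pgi_snps)))
  v1 <- ref_pop1$variants; v2 <- ref_pop2$variants
  sd1 <- std_dosage(ref_pop1, hard_calls); sd2 <- std_dosage(ref_pop2, hard_calls)
  w <- window_kb * 1000
  rows <- vector("list", nrow(pgi_snps))
  n_excluded <- 0L
  for (k in seq_len(nrow(pgi_snps))) {
    id <- pgi_snps$id[k]
    i1 <- match(id, v1$id); i2 <- match(id, v2$id)
    if (is.na(i1) || is.na(i2)) stop("PGI-SNP absent from a reference panel: ", id)
    cand <- candidates[[id]]
    if (!is.null(cand)) {
      cpos <- match(cand, v1$id)
      cand <- cand[abs(v1$pos[cpos] - v1$pos[i1]) <= w &
                     v1$chrom[cpos] == v1$chrom[i1]]
    }
    if (is.null(cand) || length(cand) == 0) { n_excluded <- n_excluded + 1L; next }
    c1 <- match(cand, v1$id); c2 <- match(cand, v2$id)
    if (anyNA(c2)) stop("candidate SNP absent from population-2 panel")
    r1 <- drop(crossprod(sd1$Z[, c1, drop = FALSE], sd1$Z[, i1])) / (sd1$n - 1)
    r2 <- drop(crossprod(sd2$Z[, c2, drop = FALSE], sd2$Z[, i2])) / (sd2$n - 1)
    p1 <- sd1$freq[i1]; p2 <- sd2$freq[i2]
    rows[[k]] <- data.frame(id = id, mean_r2_pop1 = mean(r1^2),
                            mean_r1r2 = mean(r1 * r2),
                            maf_pop1 = min(p1, 1 - p1),
                            maf_pop2 = min(p2, 1 - p2),
                            beta_hat = pgi_snps$beta_hat[k],
                            n_candidates = length(cand),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) stop("every PGI-SNP lacked in-window candidates")
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("ld_summary", class(out))
  out
}

#' Expected relative accuracy from cross-population LD/MAF summaries
#'
#' Evaluates the theoretical relative accuracy
#' \deqn{RA_{exp} = \frac{\rho_b^2 h_2^2}{h_1^2} \times
#'   \frac{\left(\sum_k \overline{r_{k,1} r_{k,2}}
#'     \sqrt{p_{k,2} q_{k,2} / (p_{k,1} q_{k,1})}\right)^2}
#'   {\left(\sum_k \overline{r_{k,1}^2}\right)^2} \times
#'   \frac{\sum_k p_{k,1} q_{k,1} \hat\beta_k^2}
#'   {\sum_k p_{k,2} q_{k,2} \hat\beta_k^2}}
#' with `q = 1 - p`. The numerator and denominator LD sums are each squared:
#' this bracketing is the one that reproduces the exact out-of-sample
#' R-squared ratio of a one-tag/one-causal system (it arises because the
#' PGI-phenotype covariance sum over SNPs is squared in R-squared, while the
#' PGI variance supplies the unsquared `p q beta^2` sums). The effects
#' factor `rho_b^2 h_2^2 / h_1^2` defaults to 1.
#'
#' @param summary an `ld_summary` data.frame.
#' @param effects_factor the `rho_b^2 h2^2/h1^2` multiplier (default 1).
#' @param snp_set_size optional requested top-set size, stored in the output.
#' @return object of class `expected_ra`: `factor_effects`,
#'   `factor_ld_maf`, `factor_varscale`, `ra_expected`, `snp_set_size`,
#'   `M_T` (number of summed SNPs).
#' @export
expected_ra <- function(summary, effects_factor = 1, snp_set_size = NA) {
  if (nrow(summary) == 0) stop("empty LD summary")
  pq1 <- summary$maf_pop1 * (1 - summary$maf_pop1)
  pq2 <- summary$maf_pop2 * (1 - summary$maf_pop2)
  num_ld <- sum(summary$mean_r1r2 * sqrt(pq2 / pq1))
  den_ld <- sum(summary$mean_r2_pop1)
  den_var <- sum(pq2 * summary$beta_hat^2)
  if (den_ld == 0 || den_var == 0 || sum(pq1 * summary$beta_hat^2) == 0)
    stop("zero denominator sum in the expected-accuracy model")
  factor_ld_maf <- (num_ld / den_ld)^2
  factor_varscale <- sum(pq1 * summary$beta_hat^2) / den_var
  structure(list(factor_effects = effects_factor,
                 factor_ld_maf = factor_ld_maf,
                 factor_varscale = factor_varscale,
                 ra_expected = effects_factor * factor_ld_maf * factor_varscale,
                 snp_set_size = snp_set_size, M_T = nrow(summary)),
            class = "expected_ra")
}

#' @export
print.expected_ra <- function(x, ...) {
  cat(sprintf(
    "expected_ra: %.4f (effects %.3f x LD/MAF %.4f x var-scale %.4f; M_T = %d)\n",
    x$ra_expected, x$factor_effects, x$factor_ld_maf, x$factor_varscale, x$M_T))
  invisible(x)
}

#' Expected relative accuracy across top-SNP set sizes
#'
#' Re-runs clumping, candidate selection, LD summarization and the
#' expected-accuracy model for each requested top-SNP set size.
#'
#' @param sumstats discovery summary statistics.
#' @param ref_pop1,ref_pop2 reference panels (shared allele coding).
#' @param set_sizes integer vector of top-set sizes
#'   (default `c(100, 1000, 10000)`).
#' @param effects_factor passed to [expected_ra()].
#' @param clump_window_kb,clump_r2,clump_p clumping parameters.
#' @param candidate_window_kb,candidate_r2 candidate-selection parameters.
#' @return data.frame with one row per set size: `snp_set_size`, `M_T`,
#'   `factor_ld_maf`, `factor_varscale`, `ra_expected`.
#' @export
stability_curve <- function(sumstats, ref_pop1, ref_pop2,
                            set_sizes = c(100, 1000, 10000),
                            effects_factor = 1,
                            clump_window_kb = 2000, clump_r2 = 0.01,
                            clump_p = 0.5, candidate_window_kb = 100,
                            candidate_r2 = 0.45) {
  qc <- qc_common_snps(list(ref_pop1, ref_pop2))
  ss <- sumstats[sumstats$id %in% qc, , drop = FALSE]
  cl <- clump(ss, ref_pop1, clump_window_kb, clump_r2, clump_p)
  rows <- lapply(set_sizes, function(k) {
    ids <- suppressWarnings(top_snps(cl, k))
    cand <- select_candidate_causal(ids, ref_pop1, qc,
                                    candidate_window_kb, candidate_r2)
    lds <- ld_summaries(
      data.frame(id = ids, beta_hat = ss$beta[match(ids, ss$id)]),
      cand, ref_pop1, ref_pop2, candidate_window_kb)
    e <- expected_ra(lds, effects_factor, snp_set_size = k)
    data.frame(snp_set_size = k, M_T = e$M_T,
               factor_ld_maf = e$factor_ld_maf,
               factor_varscale = e$factor_varscale,
               ra_expected = e$ra_expected)
  })
  do.call(rbind, rows)
}
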