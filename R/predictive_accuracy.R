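#' Incremental R-squared of a PGI over a covariate-only model
#'
#' `R^2(y ~ covariates + PGI) - R^2(y ~ covariates)`, both by OLS. An
#' intercept is always included. The increment may be slightly negative by
#' sampling noise and is returned as computed.
#'
#' @param y numeric phenotype vector (typically residualized).
#' @param pgi numeric PGI vector aligned with `y`.
#' @param covars optional numeric matrix/data.frame of covariates.
#' @return the incremental R-squared (scalar).
#' @export
incremental_r2 <- function(y, pgi, covars = NULL) {
  ok <- stats::complete.cases(y, pgi, covars)
  y <- y[ok]; pgi <- pgi[ok]
  n <- length(y)
  if (is.null(covars)) {
    if (n < 3) stop("need at least 3 complete observations")
    return(stats::cor(y, pgi)^2)
  }
  X <- as.matrix(covars)[ok, , drop = FALSE]
  if (n <= ncol(X) + 2) stop("need n > n_covariates + 2 complete observations")
  X1 <- cbind(`(Intercept)` = 1, X)
  q <- qr(X1)
  if (q$rank < ncol(X1)) {
    bad <- colnames(X1)[q$pivot[(q$rank + 1):ncol(X1)]]
    stop("rank-deficient covariate matrix; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("phenotype has zero variance")
  r_base <- qr.resid(q, y)
  r2_base <- 1 - sum(r_base^2) / tss
  q2 <- qr(cbind(X1, pgi = pgi))
  r2_full <- 1 - sum(qr.resid(q2, y)^2) / tss
  r2_full - r2_base
}

#' Observed relative accuracy
#'
#' Ratio of the target-ancestry incremental R-squared to the reference
#' incremental R-squared.
#'
#' @param r2_target,r2_ref incremental R-squared values.
#' @return `r2_target / r2_ref`.
#' @export
relative_accuracy <- function(r2_target, r2_ref) {
  if (!is.finite(r2_ref) || r2_ref <= 0)
    stop("relative accuracy undefined: reference incremental R^2 <= 0")
  r2_target / r2_ref
}

#' Percentile bootstrap confidence interval
#'
#' Resamples rows of `data` with replacement, independently within each
#' level of `groups` when given, and takes the 2.5th and 97.5th percentiles
#' of the replicate statistics. Replicates where the statistic is undefined
#' (error or non-finite) are dropped; if more than 10% are undefined the
#' result is flagged.
#'
#' @param data a data.frame of per-sample records.
#' @param statistic `function(data) -> scalar`.
#' @param B number of replications (default 1000).
#' @param seed integer seed.
#' @param groups optional vector (length `nrow(data)`) of resampling strata.
#' @param level confidence level (default 0.95).
#' @return list `estimate`, `ci_low`, `ci_high`, `replicates`,
#'   `n_undefined`, `flagged`.
#' @export
bootstrap_ci <- function(data, statistic, B = 1000, seed = NULL, groups = NULL,
                         level = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  est <- statistic(data)
  idx_groups <- if (is.null(groups)) list(seq_len(n)) else
    split(seq_len(n), groups)
  reps <- vapply(seq_len(B), function(b) {
    take <- unlist(lapply(idx_groups, function(i)
      i[sample.int(length(i), replace = TRUE)]), use.names = FALSE)
    tryCatch(as.numeric(statistic(data[take, , drop = FALSE])),
             error = function(e) NA_real_)
  }, numeric(1))
  ok <- is.finite(reps)
  n_undef <- sum(!ok)
  flagged <- n_undef > 0.1 * B
  if (flagged)
    warning("statistic undefined in ", n_undef, "/", B,
            " bootstrap replicates; CI computed over the defined ones")
  if (!any(ok)) stop("statistic undefined in every bootstrap replicate")
  a <- (1 - level) / 2
  ci <- stats::quantile(reps[ok], c(a, 1 - a), names = FALSE, type = 7)
  list(estimate = est, ci_low = ci[1], ci_high = ci[2],
       replicates = reps, n_undefined = n_undef, flagged = flagged)
}

# internal fast incremental R^2 used inside resampling loops
.inc_r2 <- function(y, pgi, X = NULL) {
  if (is.null(X)) return(stats::cor(y, pgi)^2)
  q <- qr(cbind(1, X))
  tss <- sum((y - mean(y))^2)
  r2b <- 1 - sum(qr.resid(q, y)^2) / tss
  r2f <- 1 - sum(qr.resid(qr(cbind(1, X, pgi)), y)^2) / tss
  r2f - r2b
}

#' Estimate observed relative accuracy with a bootstrap CI
#'
#' Computes per-ancestry incremental R-squared and their ratio
#' (target over reference), with a percentile bootstrap CI in which target
#' and reference individuals are resampled independently.
#'
#' @param df data.frame with columns `y`, `pgi`, `ancestry`, plus optional
#'   covariate columns named in `covar_cols`.
#' @param target,ref ancestry labels of the target and reference groups.
#' @param covar_cols character vector of covariate column names (optional).
#' @param B bootstrap replications (default 1000).
#' @param seed integer seed.
#' @param phenotype label stored in the output.
#' @return one-row data.frame of class `ra_estimate`: `phenotype`,
#'   `ancestry`, `r2_ref`, `r2_target`, `ra_obs`, `ci_low`, `ci_high`,
#'   `n_target`, `n_ref`, `B`.
#' @export
estimate_ra_obs <- function(df, target, ref, covar_cols = NULL, B = 1000,
                            seed = NULL, phenotype = "trait") {
  stopifnot(all(c("y", "pgi", "ancestry") %in% names(df)))
  df <- df[df$ancestry %in% c(target, ref), , drop = FALSE]
  getX <- function(d) if (is.null(covar_cols)) NULL else
    as.matrix(d[, covar_cols, drop = FALSE])
  stat <- function(d) {
    dt <- d[d$ancestry == target, , drop = FALSE]
    dr <- d[d$ancestry == ref, , drop = FALSE]
    r2t <- .inc_r2(dt$y, dt$pgi, getX(dt))
    r2r <- .inc_r2(dr$y, dr$pgi, getX(dr))
    if (r2r <= 0) stop("reference incremental R^2 <= 0")
    r2t / r2r
  }
  bs <- bootstrap_ci(df, stat, B = B, seed = seed, groups = df$ancestry)
  dt <- df[df$ancestry == target, ]; dr <- df[df$ancestry == ref, ]
  r2t <- .inc_r2(dt$y, dt$pgi, getX(dt))
  r2r <- .inc_r2(dr$y, dr$pgi, getX(dr))
  out <- data.frame(phenotype = phenotype, ancestry = target,
                    r2_ref = r2r, r2_target = r2t,
                    ra_obs = relative_accuracy(r2t, r2r),
                    ci_low = bs$ci_low, ci_high = bs$ci_high,
                    n_target = nrow(dt), n_ref = nrow(dr), B = B,
                    stringsAsFactors = FALSE)
  class(out) <- c("ra_estimate", class(out))
  out
}

#' Paired bootstrap test for a difference in relative accuracy
#'
#' Two PGIs scored on the same individuals (e.g. family-based vs standard)
#' are compared by resampling the same individuals for both PGIs in every
#' replicate and recomputing each relative accuracy. The two-sided p-value
#' is `2 * min(fraction of replicate differences <= 0, fraction >= 0)`,
#' clamped to `[2/B, 1]`.
#'
#' @param df data.frame with `y`, `pgi_a`, `pgi_b`, `ancestry` and optional
#'   covariate columns.
#' @param target,ref ancestry labels.
#' @param covar_cols optional covariate column names.
#' @param B bootstrap replications.
#' @param seed integer seed.
#' @return list `delta_ra` (RA of `pgi_a` minus RA of `pgi_b`), `p_value`,
#'   `replicates`.
#' @export
paired_bootstrap_ra_test <- function(df, target, ref, covar_cols = NULL,
                                     B = 1000, seed = NULL) {
  stopifnot(all(c("y", "pgi_a", "pgi_b", "ancestry") %in% names(df)))
  df <- df[df$ancestry %in% c(target, ref), , drop = FALSE]
  getX <- function(d) if (is.null(covar_cols)) NULL else
    as.matrix(d[, covar_cols, drop = FALSE])
  ra_of <- function(d, col) {
    dt <- d[d$ancestry == target, ]; dr <- d[d$ancestry == ref, ]
    r2r <- .inc_r2(dr$y, dr[[col]], getX(dr))
    if (r2r <= 0) stop("reference incremental R^2 <= 0")
    .inc_r2(dt$y, dt[[col]], getX(dt)) / r2r
  }
  stat <- function(d) ra_of(d, "pgi_a") - ra_of(d, "pgi_b")
  bs <- bootstrap_ci(df, stat, B = B, seed = seed, groups = df$ancestry)
  reps <- bs$replicates[is.finite(bs$replicates)]
  if (stats::sd(reps) == 0 && all(reps == 0)) {
    p <- 1
  } else {
    p <- 2 * min(mean(reps <= 0), mean(reps >= 0))
    p <- min(max(p, 2 / B), 1)
  }
  list(delta_ra = bs$estimate, p_value = p, replicates = bs$replicates,
       ci_low = bs$ci_low, ci_high = bs$ci_high)
}

#' Leave-one-out jackknife mean and standard error
#'
#' For a vector of per-phenotype estimates, returns the arithmetic mean and
#' the leave-one-out jackknife SE
#' `sqrt(((n-1)/n) * sum((theta_(-i) - theta_(.))^2))`.
#'
#' @param values numeric vector (n >= 2).
#' @param group optional label stored in the output.
#' @return data.frame `group`, `mean`, `se_jackknife`, `n_phenotypes`.
#' @export
jackknife_mean_se <- function(values, group = "all") {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("jackknife needs at least 2 values")
  loo <- (sum(values) - values) / (n - 1)
  se <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  data.frame(group = group, mean = mean(values), se_jackknife = se,
             n_phenotypes = n, stringsAsFactors = FALSE)
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Wraps [stats::oneway.test()] (`var.equal = FALSE`), i.e. Welch's F with
#' the Satterthwaite denominator degrees of freedom.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2, nonzero
#'   variance).
#' @return list `F`, `df1`, `df2`, `p`.
#' @export
welch_anova <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(vapply(groups, length, 1L) < 2)) stop("every group needs n >= 2")
  if (any(vapply(groups, stats::var, 1) == 0))
    stop("zero-variance group: Welch's ANOVA undefined")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  ft <- stats::oneway.test(y ~ g, var.equal = FALSE)
  list(F = unname(ft$statistic), df1 = unname(ft$parameter[1]),
       df2 = unname(ft$parameter[2]), p = unname(ft$p.value))
}

#' Benjamini-Hochberg adjustment with rejection flags
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @param fdr target false-discovery rate (default 0.05).
#' @return list `adjusted` (BH-adjusted p-values) and `reject` (logical).
#' @export
bh_adjust <- function(pvals, fdr = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  adj <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adj, reject = !is.na(adj) & adj <= fdr)
}
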