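#' Gate phenotypes for the loss-of-accuracy decomposition
#'
#' The decomposition is only meaningful when the observed relative accuracy
#' is statistically below one; a phenotype-ancestry pair is retained when
#' the upper bound of its 95% bootstrap CI is below 1.
#'
#' @param ra a data.frame of `ra_estimate` rows (with `ci_high`).
#' @return the eligible subset.
#' @export
gate_phenotypes <- function(ra) {
  ra[!is.na(ra$ci_high) & ra$ci_high < 1, , drop = FALSE]
}

#' Share of the observed accuracy loss explained by the model
#'
#' `LoA = (1 - ra_expected) / (1 - ra_obs) * 100` percent. Values above 100
#' (observed loss smaller than the expected loss) are reported as computed.
#'
#' @param ra_obs observed relative accuracy (must be `< 1`).
#' @param ra_expected model-expected relative accuracy.
#' @return the explained share, in percent.
#' @export
compute_loa <- function(ra_obs, ra_expected) {
  if (any(ra_obs >= 1))
    stop("LoA undefined for ra_obs >= 1 (gate violated)")
  (1 - ra_expected) / (1 - ra_obs) * 100
}

#' Adjust the expected relative accuracy for heritability differences
#'
#' Multiplies the expected relative accuracy by the ratio of the target to
#' reference SNP heritability. The SE is propagated by the delta method
#' treating the three inputs as independent:
#' `(se/f)^2 = (se_ra/ra)^2 + (se_t/h2_t)^2 + (se_r/h2_r)^2`.
#'
#' @param ra_expected expected relative accuracy (scalar).
#' @param h2_target,h2_ref lists/rows with `h2` and `se` (reference `h2 > 0`).
#' @param se_expected optional SE of `ra_expected` (default 0).
#' @return list `ra_expected` (adjusted) and `se`.
#' @export
adjust_for_h2 <- function(ra_expected, h2_target, h2_ref, se_expected = 0) {
  if (!is.finite(h2_ref$h2) || h2_ref$h2 <= 0)
    stop("reference heritability must be positive")
  adj <- ra_expected * h2_target$h2 / h2_ref$h2
  rel2 <- (if (ra_expected > 0) (se_expected / ra_expected)^2 else 0) +
    (if (h2_target$h2 > 0) (h2_target$se / h2_target$h2)^2 else 0) +
    (h2_ref$se / h2_ref$h2)^2
  list(ra_expected = adj, se = abs(adj) * sqrt(rel2))
}

#' Delta-method standard error of the explained-loss percentage
#'
#' First-order propagation through `(1 - ra_expected)/(1 - ra_obs) * 100`,
#' treating the two relative accuracies as independent (they are computed
#' from disjoint data: target-cohort regressions versus reference-panel LD
#' with discovery betas):
#' `SE = 100 * sqrt((se_exp/(1-ra_obs))^2 +
#'       ((1-ra_exp) * se_obs / (1-ra_obs)^2)^2)`.
#'
#' @param ra_obs,se_obs observed relative accuracy and its SE (`ra_obs < 1`).
#' @param ra_expected,se_expected expected relative accuracy and its SE.
#' @return list `se`, `ci_low`, `ci_high` (95% normal interval around the
#'   point estimate).
#' @export
loa_se_delta <- function(ra_obs, se_obs, ra_expected, se_expected) {
  if (ra_obs >= 1) stop("delta-method SE undefined for ra_obs >= 1")
  stopifnot(se_obs >= 0, se_expected >= 0)
  loa <- compute_loa(ra_obs, ra_expected)
  se <- 100 * sqrt((se_expected / (1 - ra_obs))^2 +
                     ((1 - ra_expected) * se_obs / (1 - ra_obs)^2)^2)
  list(loa = loa, se = se, ci_low = loa - 1.96 * se, ci_high = loa + 1.96 * se)
}

#' Log-scale Z-test comparing explained-loss estimates across cohorts
#'
#' `z = (ln LoA_a - ln LoA_b) / sqrt((se_a/LoA_a)^2 + (se_b/LoA_b)^2)` with
#' a two-sided normal p-value. Both estimates must be positive.
#'
#' @param loa_a,loa_b lists/rows with `loa` and `se`.
#' @return list `z`, `p`.
#' @export
cross_cohort_test <- function(loa_a, loa_b) {
  if (loa_a$loa <= 0 || loa_b$loa <= 0)
    stop("log-scale comparison needs positive LoA estimates")
  z <- (log(loa_a$loa) - log(loa_b$loa)) /
    sqrt((loa_a$se / loa_a$loa)^2 + (loa_b$se / loa_b$loa)^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
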