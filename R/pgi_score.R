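#' Compute a polygenic index from dosages and a weight table
#'
#' The raw score is the weighted sum of counted-allele dosages over the
#' weight-table variants found in the panel. Missing dosages are imputed to
#' the variant's in-sample mean. The standardized score is the within-sample
#' z-score, matching the convention of standardizing within each
#' ancestry-by-cohort analysis sample.
#'
#' @param panel a `genotype_panel`.
#' @param weights weight table (`id`, `effect_allele`, `other_allele`,
#'   `weight`). Aligned to the panel with [align_alleles()] unless
#'   `aligned = TRUE`.
#' @param aligned set `TRUE` if `weights` is already allele-aligned.
#' @return data.frame `sample_id`, `raw`, `standardized`, with attributes
#'   `n_variants_used` and `coverage` (fraction of weight-table variants
#'   found).
#' @export
compute_pgi <- function(panel, weights, aligned = FALSE) {
  n_input <- nrow(weights)
  if (!aligned) weights <- align_alleles(weights, panel)
  idx <- match(weights$id, panel$variants$id)
  ok <- !is.na(idx)
  coverage <- sum(ok) / n_input
  if (sum(ok) == 0) stop("no weight-table variants found in the panel")
  if (coverage < 0.5)
    warning(sprintf("low coverage: only %.1f%% of weight-table variants found",
                    100 * coverage))
  X <- panel$dosages[, idx[ok], drop = FALSE]
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mu[j]
  }
  raw <- drop(X %*% weights$weight[ok])
  # population (1/n) standard deviation, the usual scoring-tool convention
  s <- stats::sd(raw) * sqrt((length(raw) - 1) / length(raw))
  std <- if (s > 0) (raw - mean(raw)) / s else raw * 0
  out <- data.frame(sample_id = panel$samples, raw = raw, standardized = std,
                    stringsAsFactors = FALSE)
  attr(out, "n_variants_used") <- sum(ok)
  attr(out, "coverage") <- coverage
  out
}
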