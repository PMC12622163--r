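#' Fit a PCA ancestry model on a labelled reference panel
#'
#' PCA is fitted on the reference panel only (missing dosages mean-imputed,
#' columns centered and scaled by their reference standard deviation), and
#' the per-ancestry mean and standard deviation of each PC score is recorded.
#' Study samples are later projected onto this space by [assign_ancestry()].
#'
#' @param reference a `genotype_panel` with ancestry labels (>= 2 ancestries,
#'   >= 3 samples each).
#' @param n_pcs number of principal components (default 10).
#' @return an object of class `ancestry_model`.
#' @export
fit_ancestry_model <- function(reference, n_pcs = 10) {
  if (is.null(reference$ancestry))
    stop("reference panel must carry ancestry labels")
  tab <- table(reference$ancestry)
  if (length(tab) < 2) stop("need at least two labelled ancestries")
  if (any(tab < 3))
    stop("every reference ancestry needs >= 3 samples (SD undefined): ",
         paste(names(tab)[tab < 3], collapse = ", "))
  X <- reference$dosages
  mu <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mu[j]
  sd <- apply(X, 2, stats::sd)
  keep <- sd > 0
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep], "-"),
              2, sd[keep], "/")
  n_pcs <- min(n_pcs, ncol(Xs), nrow(Xs) - 1)
  sv <- svd(Xs, nu = 0, nv = n_pcs)
  loadings <- sv$v[, seq_len(n_pcs), drop = FALSE]
  scores <- Xs %*% loadings
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  grp <- split(seq_len(nrow(scores)), reference$ancestry)
  pc_mean <- t(vapply(grp, function(i) colMeans(scores[i, , drop = FALSE]),
                      numeric(n_pcs)))
  pc_sd <- t(vapply(grp, function(i) apply(scores[i, , drop = FALSE], 2, stats::sd),
                    numeric(n_pcs)))
  if (any(pc_sd <= 0)) stop("zero within-ancestry PC variance in the reference")
  structure(list(variant_ids = reference$variants$id[keep],
                 center = mu[keep], scale = sd[keep],
                 loadings = loadings, n_pcs = n_pcs,
                 ancestries = rownames(pc_mean),
                 pc_mean = pc_mean, pc_sd = pc_sd),
            class = "ancestry_model")
}

project_panel <- function(model, panel) {
  idx <- match(model$variant_ids, panel$variants$id)
  found <- !is.na(idx)
  if (!any(found)) stop("panel shares no variants with the ancestry model")
  n <- length(panel$samples)
  Xs <- matrix(0, n, length(model$variant_ids))   # missing variants -> 0 after scaling
  X <- panel$dosages[, idx[found], drop = FALSE]
  for (j in seq_len(ncol(X))) {                   # missing dosages -> reference mean
    x <- X[, j]
    x[is.na(x)] <- model$center[found][j]
    Xs[, which(found)[j]] <- (x - model$center[found][j]) / model$scale[found][j]
  }
  scores <- Xs %*% model$loadings
  colnames(scores) <- paste0("PC", seq_len(model$n_pcs))
  attr(scores, "fraction_missing_variants") <- mean(!found)
  scores
}

#' Assign samples to genetic ancestries by PC projection
#'
#' A sample is assigned to an ancestry if each of its projected PCs lies
#' within `sd_limit` reference standard deviations of that ancestry's
#' reference mean. Samples matching no ancestry are `"UNASSIGNED"`; samples
#' matching several are assigned to the ancestry with the smallest
#' standardized Euclidean distance, and the ambiguity is counted in the
#' report attribute.
#'
#' @param model an `ancestry_model`.
#' @param panel a `genotype_panel` sharing the model's variants.
#' @param sd_limit per-PC standard-deviation window (default 4).
#' @return character vector of labels, with an `"assignment"` report
#'   attribute (`n_unassigned`, `n_ambiguous`, fraction of model variants
#'   missing from the panel).
#' @export
assign_ancestry <- function(model, panel, sd_limit = 4) {
  scores <- project_panel(model, panel)
  n <- nrow(scores); A <- length(model$ancestries)
  dist2 <- matrix(0, n, A)
  within <- matrix(TRUE, n, A)
  for (a in seq_len(A)) {
    z <- sweep(sweep(scores, 2, model$pc_mean[a, ], "-"),
               2, model$pc_sd[a, ], "/")
    within[, a] <- apply(abs(z) <= sd_limit, 1, all)
    dist2[, a] <- rowSums(z^2)
  }
  nmatch <- rowSums(within)
  labels <- rep("UNASSIGNED", n)
  one <- nmatch == 1
  labels[one] <- model$ancestries[apply(within[one, , drop = FALSE], 1, which)]
  multi <- nmatch > 1
  if (any(multi)) {
    d2 <- dist2[multi, , drop = FALSE]
    d2[!within[multi, , drop = FALSE]] <- Inf
    labels[multi] <- model$ancestries[apply(d2, 1, which.min)]
  }
  names(labels) <- panel$samples
  attr(labels, "assignment") <- list(
    n_unassigned = sum(nmatch == 0), n_ambiguous = sum(multi),
    fraction_missing_variants = attr(scores, "fraction_missing_variants"))
  labels
}

#' Greedy windowed LD pruning
#'
#' Standard rolling-window greedy pruning: within each window (a span of
#' `window_bp` starting at the current variant), variants are scanned left to
#' right and a variant is removed if its squared correlation with any
#' retained variant in the window exceeds `r2_max`. The window start then
#' advances by `step_variants`.
#'
#' @param panel a `genotype_panel` with position-sorted variants.
#' @param window_bp window span in base pairs.
#' @param step_variants window increment in variants.
#' @param r2_max maximum allowed squared correlation.
#' @return character vector of retained variant ids.
#' @export
ld_prune <- function(panel, window_bp = 1e6, step_variants = 5, r2_max = 0.1) {
  pos <- panel$variants$pos
  if (is.unsorted(pos)) stop("variants must be position-sorted")
  m <- length(pos)
  X <- panel$dosages
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mu[j]
  }
  Xs <- standardize_columns(X)
  n <- nrow(Xs)
  keep <- rep(TRUE, m)
  start <- 1L
  while (start <= m) {
    end <- start
    while (end < m && pos[end + 1] - pos[start] <= window_bp) end <- end + 1L
    win <- start:end
    for (j in win) {
      if (!keep[j]) next
      prior <- win[win < j & keep[win]]
      if (length(prior) == 0) next
      r <- crossprod(Xs[, prior, drop = FALSE], Xs[, j]) / (n - 1)
      if (any(r^2 > r2_max)) keep[j] <- FALSE
    }
    start <- start + step_variants
  }
  panel$variants$id[keep]
}

#' Genomic relatedness matrix (VanRaden)
#'
#' Dosages are centered at `2p` and scaled by `sqrt(2p(1-p))` with `p` the
#' in-sample allele frequency; the GRM is the average cross-product over
#' variants. Missing dosages are mean-imputed. Monomorphic variants are
#' skipped.
#'
#' @param panel a `genotype_panel`.
#' @return an `n x n` relatedness matrix.
#' @export
compute_grm <- function(panel) {
  X <- panel$dosages
  p <- colMeans(X, na.rm = TRUE) / 2
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- 2 * p[j]
  keep <- p > 0 & p < 1
  Xc <- sweep(X[, keep, drop = FALSE], 2, 2 * p[keep], "-")
  Xc <- sweep(Xc, 2, sqrt(2 * p[keep] * (1 - p[keep])), "/")
  G <- tcrossprod(Xc) / sum(keep)
  dimnames(G) <- list(panel$samples, panel$samples)
  G
}

# remove one member of each pair with relatedness > threshold:
# higher missingness first, then lexicographically larger sample id
relatedness_filter <- function(grm, missingness, threshold = 0.05) {
  ids <- rownames(grm)
  removed <- character(0)
  repeat {
    G <- grm
    diag(G) <- 0
    alive <- !(ids %in% removed)
    G[!alive, ] <- 0; G[, !alive] <- 0
    hit <- which(G > threshold, arr.ind = TRUE)
    if (nrow(hit) == 0) break
    i <- hit[1, 1]; j <- hit[1, 2]
    pick <- if (missingness[i] > missingness[j]) i
            else if (missingness[j] > missingness[i]) j
            else if (ids[i] > ids[j]) i else j
    removed <- c(removed, ids[pick])
  }
  removed
}

# Exact Hardy-Weinberg test (standard two-sided exact test on het counts)
hwe_exact_p <- function(n_het, n_hom1, n_hom2) {
  n_rare <- 2 * min(n_hom1, n_hom2) + n_het
  n <- n_hom1 + n_het + n_hom2
  if (n == 0) return(1)
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  hom_r <- (n_rare - hets) / 2
  hom_c <- n - hets - hom_r
  logp <- -lgamma(hets + 1) - lgamma(hom_r + 1) - lgamma(hom_c + 1) +
    hets * log(2)
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- match(n_het, hets)
  if (is.na(obs)) return(1)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

hwe_pvalues <- function(panel) {
  hard <- round(panel$dosages)
  vapply(seq_len(ncol(hard)), function(j) {
    g <- hard[, j]; g <- g[!is.na(g)]
    hwe_exact_p(sum(g == 1), sum(g == 2), sum(g == 0))
  }, numeric(1))
}

#' Build ancestry-specific principal-component controls
#'
#' For a single-ancestry panel: excludes variants failing call rate
#' (`>= 0.99`), MAF (`>= 0.01`), Hardy-Weinberg equilibrium (exact test on
#' hard calls, `p >= 1e-5`) and any configured long-range-LD regions;
#' LD-prunes the remainder (1 Mb window, step of 5 variants, `r^2 < 0.1`);
#' removes one member of each sample pair with genomic relatedness above
#' `rel_threshold`; fits PCs on the unrelated set and projects the excluded
#' relatives back.
#'
#' @param panel a `genotype_panel` (one ancestry).
#' @param long_range_ld_regions optional data.frame `chrom`, `start`, `end`
#'   in 0-based half-open (BED) coordinates; converted internally to the
#'   panel's 1-based inclusive convention.
#' @param n_pcs number of PCs (default 20).
#' @param rel_threshold relatedness cutoff (default 0.05).
#' @param window_bp,step_variants,r2_max LD-pruning parameters.
#' @return data.frame `sample_id`, `PC1..PCn`, with attributes
#'   `removed_related` (sample ids) and `n_variants_used`.
#' @export
build_pc_controls <- function(panel, long_range_ld_regions = NULL, n_pcs = 20,
                              rel_threshold = 0.05, window_bp = 1e6,
                              step_variants = 5, r2_max = 0.1) {
  X <- panel$dosages
  call_rate <- colMeans(!is.na(X))
  p <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  hwe <- hwe_pvalues(panel)
  keep <- call_rate >= 0.99 & maf >= 0.01 & hwe >= 1e-5
  if (!is.null(long_range_ld_regions)) {
    for (r in seq_len(nrow(long_range_ld_regions))) {
      reg <- long_range_ld_regions[r, ]
      # BED 0-based half-open [start, end) -> 1-based inclusive [start+1, end]
      inreg <- panel$variants$chrom == as.character(reg$chrom) &
        panel$variants$pos >= reg$start + 1 & panel$variants$pos <= reg$end
      keep <- keep & !inreg
    }
  }
  sub <- subset_panel(panel, variants = which(keep))
  kept_ids <- ld_prune(sub, window_bp, step_variants, r2_max)
  sub <- subset_panel(sub, variants = kept_ids)
  grm <- compute_grm(sub)
  missingness <- rowMeans(is.na(sub$dosages))
  removed <- relatedness_filter(grm, missingness, rel_threshold)
  unrel <- setdiff(sub$samples, removed)
  if (length(unrel) < n_pcs + 1)
    stop("fewer than ", n_pcs + 1, " unrelated samples; cannot fit ", n_pcs, " PCs")
  fitpan <- subset_panel(sub, samples = unrel)
  fitpan$ancestry <- NULL
  X <- fitpan$dosages
  mu <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mu[j]
  sd <- apply(X, 2, stats::sd)
  ok <- sd > 0
  Xs <- sweep(sweep(X[, ok, drop = FALSE], 2, mu[ok], "-"), 2, sd[ok], "/")
  n_pcs <- min(n_pcs, ncol(Xs), nrow(Xs) - 1)
  sv <- svd(Xs, nu = 0, nv = n_pcs)
  # project the full sample (including removed relatives)
  Xall <- sub$dosages[, ok, drop = FALSE]
  for (j in seq_len(ncol(Xall))) Xall[is.na(Xall[, j]), j] <- mu[ok][j]
  Sall <- sweep(sweep(Xall, 2, mu[ok], "-"), 2, sd[ok], "/") %*% sv$v
  out <- data.frame(sample_id = sub$samples, Sall, stringsAsFactors = FALSE)
  names(out) <- c("sample_id", paste0("PC", seq_len(n_pcs)))
  attr(out, "removed_related") <- removed
  attr(out, "n_variants_used") <- sum(ok)
  out
}
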