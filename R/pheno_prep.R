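#' Residualize a phenotype on demographic covariates
#'
#' Two-stage residualization. Multi-wave phenotypes: within each wave, the
#' value is regressed by OLS on sex (omitted for sex-specific traits), a
#' second-degree polynomial in age at measurement and the sex-by-age
#' interactions; residuals are standardized within wave; each sample's
#' standardized residuals are averaged over its available waves; the average
#' is residualized a second time on a third-degree birth-year polynomial,
#' sex and their interactions. Single-wave phenotypes get one OLS on sex,
#' the third-degree birth-year polynomial and interactions.
#'
#' Binary phenotypes pass through the same linear scheme (a
#' linear-probability treatment). A perfect covariate fit returns a zero
#' residual vector with a warning rather than dividing by a zero standard
#' deviation.
#'
#' @param pheno phenotype table: `sample_id`, `phenotype`, `value`, `wave`,
#'   `sex`, `birth_year` and (for multi-wave data) `age`.
#' @param sex_specific drop the sex terms (required when sex is constant).
#' @return data.frame `sample_id`, `phenotype`, `value` (residual scale),
#'   `n_waves_used`.
#' @export
residualize <- function(pheno, sex_specific = FALSE) {
  pheno <- as.data.frame(pheno)
  req <- c("sample_id", "phenotype", "value", "sex", "birth_year")
  if (!all(req %in% names(pheno)))
    stop("phenotype table must have columns: ", paste(req, collapse = ", "))
  if (!"wave" %in% names(pheno)) pheno$wave <- 1L
  out <- lapply(split(pheno, pheno$phenotype), residualize_one,
                sex_specific = sex_specific)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

design_matrix <- function(df, terms, sex_specific) {
  f <- if (sex_specific) stats::reformulate(terms)
       else stats::reformulate(c("sex", terms, paste0("sex:", terms)))
  M <- stats::model.matrix(f, df)
  q <- qr(M)
  if (q$rank < ncol(M)) {
    bad <- colnames(M)[q$pivot[(q$rank + 1):ncol(M)]]
    if (!sex_specific && stats::var(df$sex) == 0)
      stop("sex is constant in this sample; rerun with sex_specific = TRUE ",
           "(collinear columns: ", paste(bad, collapse = ", "), ")")
    stop("collinear covariate design; offending columns: ",
         paste(bad, collapse = ", "))
  }
  M
}

# covariates are centered before powers are taken: raw third powers of
# calendar years overflow double precision of the QR rank checks

ols_residuals <- function(y, M) {
  fit <- stats::lm.fit(M, y)
  r <- fit$residuals
  if (stats::sd(r) < 1e-12 * max(1, stats::sd(y))) {
    warning("covariates fit the phenotype perfectly; returning zero residuals")
    r[] <- 0
  }
  r
}

residualize_one <- function(df, sex_specific) {
  waves <- sort(unique(df$wave))
  phen <- df$phenotype[1]
  if (length(waves) > 1) {
    if (!"age" %in% names(df) || all(is.na(df$age)))
      stop("multi-wave residualization needs an 'age' column")
    per_wave <- lapply(waves, function(w) {
      d <- df[df$wave == w, , drop = FALSE]
      d <- d[stats::complete.cases(d[, c("value", "sex", "age")]), , drop = FALSE]
      if (nrow(d) < 30)
        stop("fewer than 30 complete records in wave ", w, " of ", phen)
      ac <- d$age - mean(d$age)
      d$age1 <- ac; d$age2 <- ac^2
      M <- design_matrix(d, c("age1", "age2"), sex_specific)
      r <- ols_residuals(d$value, M)
      s <- stats::sd(r)
      data.frame(sample_id = d$sample_id, r = if (s > 0) r / s else r)
    })
    allr <- do.call(rbind, per_wave)
    agg <- stats::aggregate(r ~ sample_id, allr, mean)
    nw <- stats::aggregate(r ~ sample_id, allr, length)
    base <- df[!duplicated(df$sample_id),
               c("sample_id", "sex", "birth_year"), drop = FALSE]
    d2 <- merge(agg, base, by = "sample_id")
    d2 <- d2[stats::complete.cases(d2), , drop = FALSE]
    byc <- d2$birth_year - mean(d2$birth_year)
    d2$by1 <- byc; d2$by2 <- byc^2; d2$by3 <- byc^3
    M2 <- design_matrix(d2, c("by1", "by2", "by3"), sex_specific)
    val <- ols_residuals(d2$r, M2)
    nmatch <- nw$r[match(d2$sample_id, nw$sample_id)]
    data.frame(sample_id = d2$sample_id, phenotype = phen, value = val,
               n_waves_used = nmatch, stringsAsFactors = FALSE)
  } else {
    d <- df[stats::complete.cases(df[, c("value", "sex", "birth_year")]), ,
            drop = FALSE]
    if (nrow(d) < 30) stop("fewer than 30 complete records for ", phen)
    byc <- d$birth_year - mean(d$birth_year)
    d$by1 <- byc; d$by2 <- byc^2; d$by3 <- byc^3
    M <- design_matrix(d, c("by1", "by2", "by3"), sex_specific)
    val <- ols_residuals(d$value, M)
    data.frame(sample_id = d$sample_id, phenotype = phen, value = val,
               n_waves_used = 1L, stringsAsFactors = FALSE)
  }
}
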