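#' Jaccard similarity between two signatures
#'
#' `|A intersect B| / |A union B|`, the concordance measure used to compare
#' stage-specific biomarker panels. Defined as 0 (with a flag attribute) when
#' both sets are empty.
#'
#' @param a,b [signature_set()] objects or character vectors.
#' @return Similarity in \[0, 1\].
#' @export
jaccard_similarity <- function(a, b) {
  a <- .signature_members(a); b <- .signature_members(b)
  u <- union(a, b)
  if (!length(u)) return(structure(0, both_empty = TRUE))
  length(intersect(a, b)) / length(u)
}

#' Fraction of a signature contained in a reference panel
#'
#' `|signature intersect reference| / |signature|` — e.g. the share of a
#' stage signature that is oral-typical. Undefined (NA, flagged) for an
#' empty signature.
#'
#' @param signature,reference [signature_set()] objects or character vectors.
#' @return Fraction in \[0, 1\], or flagged `NA` for an empty signature.
#' @export
overlap_fraction <- function(signature, reference) {
  s <- .signature_members(signature); r <- .signature_members(reference)
  if (!length(s)) return(structure(NA_real_, undefined = TRUE))
  length(intersect(s, r)) / length(s)
}

#' Partial Spearman correlation
#'
#' Rank-transforms `x`, `y` and every covariate column (average ranks for
#' ties), residualizes the `x` and `y` ranks on an intercept plus the
#' covariate ranks by least squares, and returns the Pearson correlation of
#' the residuals. Ranking the covariates too makes the statistic invariant to
#' monotone covariate transformations and means adjusting `x` for itself
#' yields zero. Rows with any missing value are dropped (count reported via
#' attribute).
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric matrix/data frame of covariates.
#' @return Partial Spearman rho in \[-1, 1\]; flagged `NA` when `x` or `y` is
#'   constant after ranking.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  cv <- if (is.null(covariates)) matrix(numeric(0), length(x), 0)
        else as.matrix(covariates)
  keep <- stats::complete.cases(x, y, cv)
  n_dropped <- sum(!keep)
  x <- x[keep]; y <- y[keep]; cv <- cv[keep, , drop = FALSE]
  if (length(x) <= ncol(cv) + 2L)
    stop("need more complete observations than covariates + 2")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(structure(NA_real_, undefined = TRUE, n_dropped = n_dropped))
  X <- if (ncol(cv)) cbind(1, apply(cv, 2L, rank)) else matrix(1, length(rx), 1L)
  res_x <- stats::lm.fit(X, rx)$residuals
  res_y <- stats::lm.fit(X, ry)$residuals
  # a variable fully explained by the covariates has no partial association
  # left; only numerical noise remains in its residuals, so report 0
  if (stats::sd(res_x) < 1e-8 * stats::sd(rx) ||
      stats::sd(res_y) < 1e-8 * stats::sd(ry))
    return(structure(0, residual_degenerate = TRUE, n_dropped = n_dropped))
  structure(stats::cor(res_x, res_y), n_dropped = n_dropped)
}

#' Cardiometabolic-risk rank score for microbial features
#'
#' For every feature, partial Spearman correlations (adjusted for sex, age
#' and BMI) with each health index are computed; per index, features are
#' ranked (average ranks for ties, normalized to \[0, 1\], higher rho = rank
#' closer to 1 = more risk-associated/unfavorable); ranks are averaged first
#' within each index category and then across categories into a global rank.
#' Features with a global rank above the third quartile of the rank
#' distribution are selected.
#'
#' @param abundances Samples x features numeric matrix.
#' @param indices Samples x indices numeric matrix of risk indices.
#' @param covariates Samples x covariates matrix (sex, age, BMI), or `NULL`.
#' @param index_categories Named character/factor mapping each index (column
#'   of `indices`) to a category; one category for all when `NULL`.
#' @return Data frame of class `rank_score`: per feature the global `rank`,
#'   `selected` flag, and per-index partial rho columns.
#' @export
cardiometabolic_rank <- function(abundances, indices, covariates = NULL,
                                 index_categories = NULL) {
  stopifnot(is.matrix(abundances) || is.data.frame(abundances),
            nrow(abundances) == nrow(indices))
  abundances <- as.matrix(abundances); indices <- as.matrix(indices)
  if (ncol(indices) < 2L) stop("at least two indices are required")
  if (is.null(colnames(indices)))
    colnames(indices) <- sprintf("index%d", seq_len(ncol(indices)))
  if (is.null(index_categories))
    index_categories <- setNames(rep("all", ncol(indices)), colnames(indices))
  index_categories <- index_categories[colnames(indices)]
  if (anyNA(index_categories)) stop("index_categories must cover every index")
  m <- ncol(abundances)
  rho <- matrix(NA_real_, m, ncol(indices),
                dimnames = list(colnames(abundances), colnames(indices)))
  for (j in seq_len(ncol(indices)))
    for (f in seq_len(m))
      rho[f, j] <- suppressWarnings(
        partial_spearman(abundances[, f], indices[, j], covariates))
  norm_rank <- function(v) (rank(v, ties.method = "average") - 1) / (length(v) - 1)
  per_index_rank <- apply(rho, 2L, norm_rank)
  cats <- unique(index_categories)
  cat_rank <- vapply(cats, function(cc) {
    cols <- names(index_categories)[index_categories == cc]
    rowMeans(per_index_rank[, cols, drop = FALSE])
  }, numeric(m))
  global <- rowMeans(as.matrix(cat_rank))
  q3 <- stats::quantile(global, 0.75, names = FALSE)
  out <- data.frame(feature_id = colnames(abundances) %||% sprintf("f%d", seq_len(m)),
                    rank = unname(global), selected = unname(global > q3),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(rho))
  rownames(out) <- NULL
  class(out) <- c("rank_score", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Country-adjusted disease-signature meta-analysis
#'
#' The recipe used to derive comparison panels for other diseases: per
#' cohort, each feature's arcsine-square-root abundance is regressed on the
#' disease indicator plus country dummies (the country term is dropped for
#' single-country cohorts); the standardized class coefficients are pooled by
#' inverse-variance random effects with Paule-Mandel heterogeneity (and, by
#' default, Hartung-Knapp intervals); the signature keeps features with
#' Benjamini-Hochberg `q < fdr_max` that are found (nonzero in at least one
#' sample per class) in at least `min_datasets` cohorts.
#'
#' @param profiles List of [cohort_profile()] objects.
#' @param disease Named logical vector over samples (`TRUE` = disease).
#' @param country Named character vector over samples.
#' @param fdr_max FDR threshold (default 0.1).
#' @param min_datasets Minimum cohorts a member must be found in (default 3).
#' @param hartung_knapp Use Hartung-Knapp intervals (default `TRUE`).
#' @return A [signature_set()] with the full results table attached as the
#'   `results` attribute.
#' @export
disease_signature_meta <- function(profiles, disease, country,
                                   fdr_max = 0.1, min_datasets = 3L,
                                   hartung_knapp = TRUE) {
  features <- Reduce(union, lapply(profiles, `[[`, "feature_ids"))
  rows <- list()
  for (f in features) {
    effs <- list(); found <- 0L
    for (p in profiles) {
      ids <- p$sample_ids
      x <- if (f %in% p$feature_ids) p$abundances[f, ] else setNames(rep(0, length(ids)), ids)
      y <- asin_sqrt_transform(x)
      d <- disease[ids]
      if (length(unique(d)) < 2L) next
      if (any(x[d] > 0) && any(x[!d] > 0)) found <- found + 1L
      ctry <- factor(country[ids])
      X <- if (nlevels(droplevels(ctry)) > 1L)
        stats::model.matrix(~ d + droplevels(ctry))
      else stats::model.matrix(~ d)
      if (qr(X)$rank < ncol(X) || nrow(X) - ncol(X) < 3L) next
      fit <- stats::lm.fit(X, y)
      sigma2 <- sum(fit$residuals^2) / (nrow(X) - ncol(X))
      se <- sqrt(sigma2 * chol2inv(chol(crossprod(X)))[2, 2])
      if (is.finite(se) && se > 0)
        effs[[length(effs) + 1L]] <- study_effect(fit$coefficients[2], se^2, p$cohort_id)
    }
    if (length(effs) < 2L) next
    pool <- pool_random_effects(effs, tau2_method = "PM", hartung_knapp = hartung_knapp)
    rows[[f]] <- data.frame(feature_id = f, k = pool$k, found_in = found,
                            g = pool$g, p = pool$p, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    sig <- signature_set("disease", character(0), "no analyzable features")
    attr(sig, "results") <- data.frame()
    return(sig)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$q <- bh_fdr(res$p)
  members <- res$feature_id[res$q < fdr_max & res$found_in >= min_datasets]
  sig <- signature_set("disease", members,
                       sprintf("country-adjusted PM meta-analysis, q < %g in >= %d datasets",
                               fdr_max, min_datasets))
  attr(sig, "results") <- res
  sig
}
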