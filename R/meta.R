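#' Arcsine-square-root transform of a relative abundance
#'
#' The variance-stabilizing transform applied to all relative-abundance
#' profiles before effect-size estimation and classification:
#' `asin(sqrt(p))`, in radians. Inputs within 1e-12 of the unit interval are
#' clipped to it; anything further out is a domain error.
#'
#' @param p Numeric vector of fractions in \[0, 1\].
#' @return Transformed values in \[0, pi/2\].
#' @export
asin_sqrt_transform <- function(p) {
  if (any(p < -1e-12 | p > 1 + 1e-12, na.rm = TRUE))
    stop("relative abundances must lie in [0, 1]")
  asin(sqrt(pmin(pmax(p, 0), 1)))
}

#' Hedges' g standardized mean difference between two groups
#'
#' Computes Cohen's d with the pooled (n-1 denominator) standard deviation and
#' applies Hedges' small-sample correction `J = 1 - 3/(4*df - 1)` with
#' `df = n1 + n2 - 2`. The sampling variance is
#' `J^2 * ((n1+n2)/(n1*n2) + d^2/(2*df))`. Positive g means group 1 has the
#' higher mean (convention: group 1 = CRC / late stage / right-sided).
#' When both groups are constant (pooled SD zero) the effect is returned as 0
#' with the mean-term variance only and flagged degenerate.
#'
#' @param x1,x2 Numeric vectors (each of length >= 2) of, typically,
#'   arcsine-square-root transformed abundances.
#' @param cohort_id Optional label stored on the result.
#' @return An object of class `study_effect`: a list with group summaries,
#'   `g`, `var_g` and a `degenerate` flag.
#' @export
hedges_g <- function(x1, x2, cohort_id = NA_character_) {
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2L || n2 < 2L) stop("both groups need at least two observations")
  if (anyNA(x1) || anyNA(x2)) stop("missing values not allowed")
  m1 <- mean(x1); m2 <- mean(x2)
  s1 <- stats::sd(x1); s2 <- stats::sd(x2)
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df)
  J <- 1 - 3 / (4 * df - 1)
  degenerate <- sp == 0
  d <- if (degenerate) 0 else (m1 - m2) / sp
  g <- J * d
  var_g <- J^2 * ((n1 + n2) / (n1 * n2) + d^2 / (2 * df))
  structure(list(cohort_id = cohort_id, n1 = n1, n2 = n2,
                 mean1 = m1, mean2 = m2, sd1 = s1, sd2 = s2,
                 g = g, var_g = var_g, degenerate = degenerate),
            class = "study_effect")
}

#' Construct a study effect from a precomputed estimate and variance
#'
#' Used for covariate-adjusted analyses where the per-cohort effect is a
#' regression coefficient with its squared standard error.
#'
#' @param g Effect estimate.
#' @param var_g Sampling variance (> 0).
#' @param cohort_id Optional label.
#' @param n1,n2 Optional group sizes.
#' @return A `study_effect`.
#' @export
study_effect <- function(g, var_g, cohort_id = NA_character_,
                         n1 = NA_integer_, n2 = NA_integer_) {
  stopifnot(is.finite(g), is.finite(var_g), var_g >= 0)
  structure(list(cohort_id = cohort_id, n1 = n1, n2 = n2,
                 mean1 = NA_real_, mean2 = NA_real_, sd1 = NA_real_, sd2 = NA_real_,
                 g = g, var_g = var_g, degenerate = FALSE),
            class = "study_effect")
}

#' Per-feature eligibility filter for meta-analysis
#'
#' A feature enters the meta-analysis when (a) in at least one of the two
#' class sets (pooled across cohorts) it reaches `min_prevalence` prevalence
#' and is detected in at least `min_positive` samples, and (b) at least
#' `min_studies` cohorts contribute at least `min_per_class` samples in each
#' class.
#'
#' @param abundance Named numeric vector of the feature's abundance across all
#'   samples of the contrast.
#' @param class1,class2 Character vectors of sample ids in each class.
#' @param cohort Named character vector mapping sample id to cohort id.
#' @param min_prevalence,min_positive,min_per_class,min_studies Filter
#'   thresholds (defaults 10%, 5 samples, 10 per class, 3 studies).
#' @return Logical scalar.
#' @export
feature_eligible <- function(abundance, class1, class2, cohort,
                             min_prevalence = 0.10, min_positive = 5L,
                             min_per_class = 10L, min_studies = 3L) {
  ok_class <- function(ids) {
    x <- abundance[ids]
    npos <- sum(x > 0, na.rm = TRUE)
    length(ids) > 0 && npos / length(ids) >= min_prevalence && npos >= min_positive
  }
  if (!(ok_class(class1) || ok_class(class2))) return(FALSE)
  tab1 <- table(cohort[class1]); tab2 <- table(cohort[class2])
  shared <- intersect(names(tab1), names(tab2))
  sum(tab1[shared] >= min_per_class & tab2[shared] >= min_per_class) >= min_studies
}

.reml_tau2 <- function(g, v, tol = 1e-10, max_iter = 100L) {
  t2 <- max(0, stats::var(g) - mean(v))
  for (i in seq_len(max_iter)) {
    w <- 1 / (v + t2)
    ghat <- sum(w * g) / sum(w)
    t2_new <- max(0, sum(w^2 * ((g - ghat)^2 - v)) / sum(w^2) + 1 / sum(w))
    if (abs(t2_new - t2) < tol) return(t2_new)
    t2 <- t2_new
  }
  t2
}

.pm_tau2 <- function(g, v, tol = 1e-10, max_iter = 100L) {
  k <- length(g)
  qfun <- function(t2) {
    w <- 1 / (v + t2)
    ghat <- sum(w * g) / sum(w)
    sum(w * (g - ghat)^2)
  }
  if (qfun(0) <= k - 1) return(0)
  upper <- max(v) + stats::var(g) * 10 + 1
  while (qfun(upper) > k - 1) upper <- upper * 4
  stats::uniroot(function(t2) qfun(t2) - (k - 1), c(0, upper), tol = tol,
                 maxiter = max_iter)$root
}

#' Random-effects pooling of per-cohort standardized mean differences
#'
#' Pools per-cohort effects with inverse-variance weights
#' `w_i = 1/(var_i + tau2)`. Between-study variance is estimated by iterated
#' restricted maximum likelihood (default) or by the Paule-Mandel method
#' (solving the generalized Q equation `Q(tau2) = k - 1`), both to an
#' absolute tolerance of 1e-10 (at most 100 iterations, truncated at zero).
#' With the Hartung-Knapp adjustment (default) the pooled variance is
#' `sum(w*(g - ghat)^2) / ((k-1) * sum(w))` and confidence limits and the
#' two-sided p-value come from the t distribution with `k - 1` degrees of
#' freedom; without it, the normal approximation with variance `1/sum(w)` is
#' used. Heterogeneity is summarized by Cochran's Q (fixed-effect weights)
#' and `I2 = max(0, 100*(Q - (k-1))/Q)`.
#'
#' A single study (`k = 1`) is returned with its own normal-theory interval
#' and flagged `pooled = FALSE`.
#'
#' @param effects List of `study_effect` objects (or a data frame with
#'   columns `g` and `var_g`).
#' @param tau2_method `"REML"` or `"PM"` (Paule-Mandel).
#' @param hartung_knapp Use the Hartung-Knapp adjustment (default `TRUE`).
#' @param conf_level Confidence level for the interval.
#' @return An object of class `meta_pool`: `g`, `se`, `ci_low`, `ci_high`,
#'   `tau2`, `i2`, `q_stat`, `p`, `k`, `pooled`, `method`.
#' @export
pool_random_effects <- function(effects, tau2_method = c("REML", "PM"),
                                hartung_knapp = TRUE, conf_level = 0.95) {
  tau2_method <- match.arg(tau2_method)
  if (is.data.frame(effects)) {
    g <- effects$g; v <- effects$var_g
  } else {
    g <- vapply(effects, `[[`, numeric(1), "g")
    v <- vapply(effects, `[[`, numeric(1), "var_g")
  }
  stopifnot(length(g) == length(v), all(is.finite(g)), all(is.finite(v)))
  k <- length(g)
  if (k == 0L) stop("no study effects to pool")
  alpha <- 1 - conf_level
  if (k == 1L) {
    se <- sqrt(v)
    zc <- stats::qnorm(1 - alpha / 2)
    return(structure(list(g = g, se = se, ci_low = g - zc * se, ci_high = g + zc * se,
                          tau2 = 0, i2 = 0, q_stat = 0,
                          p = 2 * stats::pnorm(-abs(g / se)),
                          k = 1L, pooled = FALSE, method = tau2_method,
                          hartung_knapp = hartung_knapp),
                     class = "meta_pool"))
  }
  if (all(v == 0)) stop("all sampling variances are zero; pooling is degenerate")
  t2 <- switch(tau2_method, REML = .reml_tau2(g, v), PM = .pm_tau2(g, v))
  w <- 1 / (v + t2)
  ghat <- sum(w * g) / sum(w)
  # Cochran's Q with fixed-effect weights, for I2
  wf <- 1 / v
  gfe <- sum(wf * g) / sum(wf)
  Q <- sum(wf * (g - gfe)^2)
  i2 <- if (Q > 0) max(0, 100 * (Q - (k - 1)) / Q) else 0
  if (hartung_knapp) {
    var_hat <- sum(w * (g - ghat)^2) / ((k - 1) * sum(w))
    se <- sqrt(var_hat)
    crit <- stats::qt(1 - alpha / 2, df = k - 1)
    p <- if (se > 0) 2 * stats::pt(-abs(ghat / se), df = k - 1) else as.numeric(ghat == 0)
  } else {
    se <- sqrt(1 / sum(w))
    crit <- stats::qnorm(1 - alpha / 2)
    p <- 2 * stats::pnorm(-abs(ghat / se))
  }
  structure(list(g = ghat, se = se, ci_low = ghat - crit * se,
                 ci_high = ghat + crit * se, tau2 = t2, i2 = i2, q_stat = Q,
                 p = p, k = k, pooled = TRUE, method = tau2_method,
                 hartung_knapp = hartung_knapp),
            class = "meta_pool")
}

#' @export
print.meta_pool <- function(x, ...) {
  cat(sprintf("Pooled SMD (k = %d, %s%s): g = %.3f [%.3f, %.3f], tau2 = %.4f, I2 = %.1f%%, p = %.3g\n",
              x$k, x$method, if (x$hartung_knapp) " + HK" else "",
              x$g, x$ci_low, x$ci_high, x$tau2, x$i2, x$p))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (q-values), as implemented by
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return q-values in the original order.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Covariate-adjusted per-cohort effect of class on a feature
#'
#' Ordinary least squares of the arcsine-square-root transformed abundance on
#' the class indicator plus age, sex and BMI within one cohort. Rows with any
#' missing covariate are dropped (the count is reported); at least
#' `min_complete` complete rows are required. The returned effect is the class
#' coefficient with its squared standard error as sampling variance, suitable
#' for [pool_random_effects()].
#'
#' @param abundance Numeric vector of relative abundances (fractions).
#' @param is_class1 Logical vector, `TRUE` for the positive-direction class.
#' @param age,bmi Numeric covariates (`NA` = missing).
#' @param sex Factor or character (`"missing"` treated as NA).
#' @param cohort_id Optional label.
#' @param min_complete Minimum complete-covariate rows (default 10).
#' @return A `study_effect` with an `n_dropped` attribute, or `NULL` (with a
#'   warning) when the cohort is skipped.
#' @export
adjusted_effect <- function(abundance, is_class1, age, sex, bmi,
                            cohort_id = NA_character_, min_complete = 10L) {
  sex <- as.character(sex)
  sex[sex == "missing"] <- NA
  keep <- !is.na(age) & !is.na(bmi) & !is.na(sex) & !is.na(abundance)
  n_dropped <- sum(!keep)
  if (sum(keep) < min_complete) {
    warning("cohort ", cohort_id, " skipped: only ", sum(keep), " complete rows")
    return(NULL)
  }
  y <- asin_sqrt_transform(abundance[keep])
  X <- cbind(1, as.numeric(is_class1[keep]), age[keep],
             as.numeric(sex[keep] == "male"), bmi[keep])
  if (qr(X)$rank < ncol(X)) {
    warning("cohort ", cohort_id, " skipped: rank-deficient design")
    return(NULL)
  }
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtX_inv[2, 2])
  if (!is.finite(se) || se == 0) {
    warning("cohort ", cohort_id, " skipped: degenerate class coefficient")
    return(NULL)
  }
  eff <- study_effect(g = unname(fit$coefficients[2]), var_g = se^2, cohort_id = cohort_id,
                      n1 = sum(is_class1[keep]), n2 = sum(!is_class1[keep]))
  attr(eff, "n_dropped") <- n_dropped
  eff
}

#' Per-feature random-effects meta-analysis across cohorts
#'
#' The pooled biomarker-discovery workhorse: for every feature passing
#' [feature_eligible()], computes per-cohort Hedges' g of
#' arcsine-square-root abundances between the two contrast classes (or, with
#' `adjust = TRUE`, the covariate-adjusted class coefficient via
#' [adjusted_effect()]), pools them with [pool_random_effects()], and applies
#' Benjamini-Hochberg correction across analyzed features. Only cohorts with
#' at least `min_per_class` samples in each class contribute effects.
#'
#' @param profiles List of [cohort_profile()] objects.
#' @param metadata A `sample_metadata` frame covering the profiled samples.
#' @param contrast Contrast string for [define_contrast()], default CRC vs
#'   control; class 1 (first set) is the positive direction.
#' @param tau2_method,hartung_knapp Passed to [pool_random_effects()].
#' @param adjust If `TRUE`, adjust per-cohort effects for age, sex and BMI.
#' @param min_per_class Per-cohort minimum class size (default 10).
#' @param min_studies Minimum cohorts for a pooled feature (default 3).
#' @return A data frame of class `meta_results`: one row per analyzed feature
#'   with `g`, `ci_low`, `ci_high`, `tau2`, `i2`, `p`, `q`, `k`.
#' @export
run_meta_analysis <- function(profiles, metadata,
                              contrast = "condition:CRC vs condition:control",
                              tau2_method = "REML", hartung_knapp = TRUE,
                              adjust = FALSE, min_per_class = 10L,
                              min_studies = 3L) {
  sets <- define_contrast(metadata, contrast)
  md <- as.data.frame(metadata)
  rownames(md) <- md$sample_id
  cohort_of <- setNames(md$cohort_id, md$sample_id)
  features <- Reduce(union, lapply(profiles, `[[`, "feature_ids"))
  # assemble one abundance row per feature on demand
  all_ab <- do.call(cbind, lapply(profiles, function(p) {
    m <- matrix(0, length(features), length(p$sample_ids),
                dimnames = list(features, p$sample_ids))
    m[p$feature_ids, ] <- p$abundances
    m
  }))
  s1 <- intersect(sets$set1, colnames(all_ab))
  s2 <- intersect(sets$set2, colnames(all_ab))
  if (!length(s1) || !length(s2)) stop("contrast classes not represented in profiles")
  tab1 <- table(cohort_of[s1]); tab2 <- table(cohort_of[s2])
  cohorts <- intersect(names(tab1)[tab1 >= min_per_class],
                       names(tab2)[tab2 >= min_per_class])
  rows <- list()
  for (f in features) {
    x <- all_ab[f, ]
    if (!feature_eligible(x, s1, s2, cohort_of, min_per_class = min_per_class,
                          min_studies = min_studies)) next
    effs <- list()
    for (cid in cohorts) {
      i1 <- s1[cohort_of[s1] == cid]; i2 <- s2[cohort_of[s2] == cid]
      e <- if (adjust) {
        ids <- c(i1, i2)
        suppressWarnings(adjusted_effect(
          x[ids], c(rep(TRUE, length(i1)), rep(FALSE, length(i2))),
          age = md[ids, "age"], sex = md[ids, "sex"], bmi = md[ids, "bmi"],
          cohort_id = cid))
      } else {
        hedges_g(asin_sqrt_transform(x[i1]), asin_sqrt_transform(x[i2]), cid)
      }
      if (!is.null(e) && e$var_g > 0) effs[[length(effs) + 1L]] <- e
    }
    if (length(effs) < max(2L, min_studies)) next
    pool <- pool_random_effects(effs, tau2_method = tau2_method,
                                hartung_knapp = hartung_knapp)
    rows[[f]] <- data.frame(feature_id = f, k = pool$k, g = pool$g,
                            ci_low = pool$ci_low, ci_high = pool$ci_high,
                            tau2 = pool$tau2, i2 = pool$i2, p = pool$p,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(structure(data.frame(), class = c("meta_results", "data.frame")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- bh_fdr(out$p)
  class(out) <- c("meta_results", "data.frame")
  out
}
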