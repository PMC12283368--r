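test_that("arcsine-square-root transform matches closed forms and clips tolerantly", {
  expect_equal(asin_sqrt_transform(0), 0)
  expect_equal(asin_sqrt_transform(1), pi / 2)
  expect_equal(asin_sqrt_transform(0.25), pi / 6)
  expect_equal(asin_sqrt_transform(1 + 1e-13), pi / 2)
  expect_error(asin_sqrt_transform(1.01), "\\[0, 1\\]")
})

test_that("Hedges' g matches the stated formulas and symmetries", {
  e <- hedges_g(c(1, 2, 3), c(4, 5, 6))
  expect_equal(e$g, -2.4)              # d = -3, J = 1 - 3/15 = 0.8
  expect_equal(e$var_g, 0.8^2 * (6 / 9 + 9 / 8))

  x <- stats::rnorm(20); y <- stats::rnorm(15, 0.5)
  expect_equal(hedges_g(x, x)$g, 0)
  a <- hedges_g(x, y); b <- hedges_g(y, x)
  expect_equal(a$g, -b$g)
  expect_equal(a$var_g, b$var_g)
  # scale equivariance
  s <- hedges_g(3.7 * x, 3.7 * y)
  expect_equal(s$g, a$g)

  # hand-formula oracle on random draws
  set.seed(2)
  for (rep in 1:10) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    x1 <- stats::rnorm(n1); x2 <- stats::rnorm(n2, 0.3)
    sp <- sqrt(((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) / (n1 + n2 - 2))
    d <- (mean(x1) - mean(x2)) / sp
    J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
    ee <- hedges_g(x1, x2)
    expect_equal(ee$g, J * d, tolerance = 1e-12)
    expect_equal(ee$var_g, J^2 * ((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2 - 2))),
                 tolerance = 1e-12)
  }

  # degenerate: zero pooled SD flagged, g = 0, variance from the mean term
  dg <- hedges_g(rep(1, 5), rep(1, 6))
  expect_true(dg$degenerate)
  expect_equal(dg$g, 0)
  expect_gt(dg$var_g, 0)
})

test_that("eligibility filter enforces prevalence, count and study rules", {
  cohort <- setNames(rep(c("c1", "c2", "c3"), each = 30), sprintf("s%02d", 1:90))
  class1 <- names(cohort)[rep(c(TRUE, FALSE), 45)]
  class2 <- setdiff(names(cohort), class1)
  x <- setNames(rep(0, 90), names(cohort))
  x[class1[1:6]] <- 0.01   # 6/45 = 13% prevalence, 6 positive samples
  expect_true(feature_eligible(x, class1, class2, cohort))
  x4 <- setNames(rep(0, 90), names(cohort)); x4[class1[1:4]] <- 0.01
  expect_false(feature_eligible(x4, class1, class2, cohort))  # five-sample rule
  # only two cohorts with >= 10 per class
  cohort2 <- cohort; cohort2[cohort2 == "c3"] <- "c2"
  expect_false(feature_eligible(x, class1, class2, cohort2,
                                min_studies = 3))
})

test_that("random-effects pooling agrees with metafor for REML and Paule-Mandel", {
  skip_if_not_installed("metafor")
  set.seed(42)
  for (rep in 1:8) {
    k <- sample(3:12, 1)
    g <- stats::rnorm(k, 0.4, 0.35)
    v <- stats::runif(k, 0.01, 0.1)
    effs <- lapply(seq_len(k), function(i) study_effect(g[i], v[i]))
    mine <- pool_random_effects(effs, "REML", hartung_knapp = TRUE)
    ref <- metafor::rma(yi = g, vi = v, method = "REML", test = "knha")
    expect_equal(mine$g, as.numeric(ref$b), tolerance = 1e-5)
    expect_equal(mine$tau2, ref$tau2, tolerance = 1e-4)
    expect_equal(mine$p, ref$pval, tolerance = 1e-4)
    expect_equal(mine$ci_low, ref$ci.lb, tolerance = 1e-4)
    expect_equal(mine$i2, ref$I2, tolerance = 0.5)

    pm <- pool_random_effects(effs, "PM", hartung_knapp = TRUE)
    ref_pm <- metafor::rma(yi = g, vi = v, method = "PM", test = "knha")
    expect_equal(pm$g, as.numeric(ref_pm$b), tolerance = 1e-3)
    expect_equal(pm$tau2, ref_pm$tau2, tolerance = 1e-3)
  }
})

test_that("pooling handles homogeneous, single-study and degenerate inputs", {
  h <- pool_random_effects(list(study_effect(0.5, 0.04), study_effect(0.5, 0.04)))
  expect_equal(h$g, 0.5)
  expect_equal(h$tau2, 0)
  expect_equal(h$i2, 0)

  # with tau2 = 0 the pooled estimate is the brute-force inverse-variance mean
  g <- c(0.31, 0.30, 0.32, 0.305); v <- c(0.05, 0.02, 0.04, 0.03)
  mine <- pool_random_effects(data.frame(g = g, var_g = v), "REML")
  expect_equal(mine$tau2, 0)
  expect_equal(mine$g, sum(g / v) / sum(1 / v), tolerance = 1e-10)

  one <- pool_random_effects(list(study_effect(0.4, 0.02)))
  expect_false(one$pooled)
  expect_equal(one$k, 1L)
  expect_lt(one$ci_low, 0.4); expect_gt(one$ci_high, 0.4)

  expect_error(pool_random_effects(list(study_effect(0.1, 0), study_effect(0.2, 0))),
               "degenerate")
  # REML and PM agree on homogeneous-variance fixtures (within 10% relative tau2)
  set.seed(5)
  g2 <- stats::rnorm(12, 0.3, 0.3); v2 <- rep(0.03, 12)
  t_reml <- pool_random_effects(data.frame(g = g2, var_g = v2), "REML")$tau2
  t_pm <- pool_random_effects(data.frame(g = g2, var_g = v2), "PM")$tau2
  expect_lt(abs(t_reml - t_pm) / max(t_reml, t_pm), 0.10)
})

test_that("covariate adjustment recovers the class effect and absorbs confounds", {
  set.seed(31)
  n <- 120
  cls <- rep(c(TRUE, FALSE), each = n / 2)
  age <- stats::rnorm(n, 60, 8)
  sex <- sample(c("female", "male"), n, TRUE)
  bmi <- stats::rnorm(n, 26, 3)

  # covariates orthogonal to class: adjusted effect ~ unadjusted coefficient
  y <- 0.02 + 0.004 * cls + stats::rnorm(n, 0, 0.002)
  ab <- pmin(pmax(sin(y)^2, 0), 1)    # invert the transform so lm sees y
  adj <- adjusted_effect(ab, cls, age, sex, bmi)
  raw_coef <- unname(coef(stats::lm(asin_sqrt_transform(ab) ~ cls))[2])
  expect_equal(adj$g, raw_coef, tolerance = 0.15)

  # abundance driven by age only: class coefficient near zero
  y2 <- 0.001 * age + stats::rnorm(n, 0, 0.001)
  ab2 <- pmin(pmax(sin(y2)^2, 0), 1)
  adj2 <- adjusted_effect(ab2, cls, age, sex, bmi)
  expect_lt(abs(adj2$g), 3 * sqrt(adj2$var_g))

  # closed-form normal equations on a tiny fixture
  ab3 <- c(0.01, 0.03, 0.02, 0.05, 0.04, 0.06, 0.02, 0.03, 0.05, 0.01, 0.04, 0.02)
  cls3 <- rep(c(TRUE, FALSE), 6)
  age3 <- c(50, 63, 58, 71, 66, 75, 52, 61, 69, 55, 72, 59)
  sex3 <- rep(c("female", "male"), each = 6)
  bmi3 <- c(22, 27, 24, 31, 20, 29, 25, 23, 30, 21, 28, 26)
  adj3 <- adjusted_effect(ab3, cls3, age3, sex3, bmi3, min_complete = 10)
  X <- cbind(1, cls3, age3, sex3 == "male", bmi3)
  beta <- solve(t(X) %*% X, t(X) %*% asin_sqrt_transform(ab3))
  expect_equal(unname(adj3$g), unname(beta[2, 1]), tolerance = 1e-10)

  # missing covariates dropped; too few complete rows -> skipped with warning
  age_na <- age; age_na[1:115] <- NA
  expect_warning(out <- adjusted_effect(ab, cls, age_na, sex, bmi), "complete")
  expect_null(out)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(77)
  p <- stats::runif(40)^2
  q <- bh_fdr(p)
  # brute-force step-up: q_(i) = min_{j>=i} m*p_(j)/j, original order restored
  o <- order(p)
  m <- length(p)
  q_brute <- numeric(m)
  q_brute[o] <- rev(cummin(rev(m * p[o] / seq_len(m))))
  expect_equal(q, pmin(q_brute, 1), tolerance = 1e-12)
  expect_true(all(diff(q[o]) >= -1e-12))   # monotone in sorted p
  expect_true(all(q >= p))
})

test_that("the meta-analysis driver flags planted features and respects direction", {
  cfg <- sim_config(n_cohorts = 4, samples_per_class = c(control = 40, CRC = 40),
                    n_features = 60, n_oral_features = 0,
                    planted_effects = c(SGB0010 = 0.9, SGB0011 = -0.9), seed = 13)
  sim <- generate_multicohort(cfg)
  res <- run_meta_analysis(sim$profiles, sim$metadata)
  expect_s3_class(res, "meta_results")
  expect_true(all(res$ci_low <= res$g & res$g <= res$ci_high))
  expect_true(all(res$tau2 >= 0 & res$i2 >= 0 & res$i2 <= 100))
  expect_true(all(res$q >= res$p - 1e-12))
  expect_gt(res$g[res$feature_id == "SGB0010"], 0)   # positive = higher in CRC
  expect_lt(res$g[res$feature_id == "SGB0011"], 0)
  expect_equal(res$k[res$feature_id == "SGB0010"], 4L)
})
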