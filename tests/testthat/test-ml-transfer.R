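light_rf <- function() rf_classifier(num_trees = 100L, mtry_grid = NULL)

test_that("rank AUC matches brute-force pairwise comparison", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc_rank(rep(0.5, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)), 0.5)
  expect_error(auc_rank(1:4, rep(TRUE, 4)), "both classes")
  set.seed(9)
  for (rep in 1:15) {
    n <- sample(10:40, 1)
    s <- sample(seq(0, 1, 0.1), n, TRUE)   # plenty of ties
    y <- stats::runif(n) > 0.5
    if (!any(y) || all(y)) next
    brute <- 0
    for (i in which(y)) for (j in which(!y))
      brute <- brute + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
    expect_equal(auc_rank(s, y), brute / (sum(y) * sum(!y)))
  }
})

test_that("feature preparation transforms, renormalizes subsets and partitions", {
  m <- rbind(o1 = c(0.3, 0.1), o2 = c(0.2, 0.1), g1 = c(0.5, 0.2), g2 = c(0, 0.6))
  colnames(m) <- c("s1", "s2")
  prof <- cohort_profile("c1", m)
  sig <- signature_set("oral", c("o1", "o2"))

  all_x <- prepare_features(prof, "all")
  expect_equal(unname(all_x["s1", "g1"]), asin(sqrt(0.5)))

  oral_x <- prepare_features(prof, "oral", sig)
  # s1's oral species sum to 0.5 -> retained values double before transform
  expect_equal(unname(oral_x["s1", "o1"]), asin(sqrt(0.6)))
  expect_equal(unname(oral_x["s1", "o2"]), asin(sqrt(0.4)))

  non_x <- prepare_features(prof, "nonoral", sig)
  expect_setequal(c(colnames(oral_x), colnames(non_x)), rownames(m))
  expect_length(intersect(colnames(oral_x), colnames(non_x)), 0)
})

test_that("per-dataset CV separates planted signal from permuted labels", {
  eff <- setNames(rep(2, 10), sprintf("SGB%04d", 21:30))
  cfg <- sim_config(n_cohorts = 1, samples_per_class = c(control = 30, CRC = 30),
                    n_features = 80, n_oral_features = 0,
                    planted_effects = eff, seed = 41)
  sim <- generate_multicohort(cfg)
  x <- prepare_features(sim$profiles[[1]], "all")
  md <- as.data.frame(sim$metadata)
  y <- md$condition[match(rownames(x), md$sample_id)] == "CRC"

  strong <- per_dataset_cv(x, y, k = 5, repeats = 3, classifier = light_rf(), seed = 1)
  expect_gte(strong$auc, 0.9)

  set.seed(8)
  null <- per_dataset_cv(x, sample(y), k = 5, repeats = 3,
                         classifier = light_rf(), seed = 1)
  expect_gte(null$auc, 0.35)
  expect_lte(null$auc, 0.65)

  # 14 cases is below the eligibility floor
  expect_error(per_dataset_cv(x[1:44, ], c(rep(TRUE, 14), rep(FALSE, 30)),
                              classifier = light_rf()), "ineligible")
})

test_that("across-dataset transfer requires signal shared between cohorts", {
  eff <- setNames(rep(2, 10), sprintf("SGB%04d", 21:30))
  shared <- generate_multicohort(sim_config(n_cohorts = 2,
    samples_per_class = c(control = 30, CRC = 30), n_features = 80,
    n_oral_features = 0, planted_effects = eff, seed = 51))
  null_sim <- generate_multicohort(sim_config(n_cohorts = 1,
    samples_per_class = c(control = 30, CRC = 30), n_features = 80,
    n_oral_features = 0, seed = 52))
  md <- as.data.frame(shared$metadata)
  xs <- lapply(shared$profiles, prepare_features)
  ys <- lapply(shared$profiles, function(p)
    md$condition[match(p$sample_ids, md$sample_id)] == "CRC")
  auc_shared <- cross_dataset(xs[[1]], ys[[1]], xs[[2]], ys[[2]],
                              classifier = light_rf(), seed = 1)
  expect_gte(auc_shared, 0.8)

  # train on a null cohort, test where the effect exists: near-chance
  md0 <- as.data.frame(null_sim$metadata)
  x0 <- prepare_features(null_sim$profiles[[1]])
  y0 <- md0$condition[match(rownames(x0), md0$sample_id)] == "CRC"
  auc_null <- cross_dataset(x0, y0, xs[[2]], ys[[2]], classifier = light_rf(), seed = 1)
  expect_gte(auc_null, 0.3); expect_lte(auc_null, 0.7)

  # training and test sets sharing samples are refused
  expect_error(cross_dataset(xs[[1]], ys[[1]], xs[[1]], ys[[1]],
                             classifier = light_rf()), "share samples")
})

test_that("LODO pools training cohorts and never leaks the held-out cohort", {
  eff <- setNames(rep(1.5, 10), sprintf("SGB%04d", 21:30))
  sim <- generate_multicohort(sim_config(n_cohorts = 3,
    samples_per_class = c(control = 25, CRC = 25), n_features = 60,
    n_oral_features = 0, planted_effects = eff, seed = 61))
  md <- as.data.frame(sim$metadata)
  xs <- setNames(lapply(sim$profiles, prepare_features),
                 vapply(sim$profiles, `[[`, "", "cohort_id"))
  ys <- setNames(lapply(sim$profiles, function(p)
    md$condition[match(p$sample_ids, md$sample_id)] == "CRC"), names(xs))
  a <- lodo(xs, ys, "cohort02", classifier = light_rf(), seed = 3)
  expect_gte(a, 0.85)
  # leakage check is structural: duplicated rowname in pool and test refused
  xs_bad <- xs
  rownames(xs_bad$cohort01)[1] <- rownames(xs$cohort02)[1]
  expect_error(lodo(xs_bad, ys, "cohort02", classifier = light_rf()), "shares samples")
})

test_that("the evaluation harness is deterministic and honors eligibility", {
  eff <- setNames(rep(1.5, 8), sprintf("SGB%04d", 11:18))
  sim <- generate_multicohort(sim_config(n_cohorts = 3,
    samples_per_class = c(control = 20, CRC = 20), n_features = 50,
    n_oral_features = 10, planted_effects = eff, seed = 71))
  e1 <- evaluate_transfer(sim$profiles, sim$metadata, mode = "lodo",
                          classifier = light_rf(), seed = 5)
  e2 <- evaluate_transfer(sim$profiles, sim$metadata, mode = "lodo",
                          classifier = light_rf(), seed = 5)
  expect_identical(e1, e2)
  expect_true(all(e1$auc >= 0 & e1$auc <= 1, na.rm = TRUE))

  # cross mode returns a train x test matrix with an empty diagonal
  cr <- evaluate_transfer(sim$profiles, sim$metadata, mode = "cross",
                          classifier = light_rf(), seed = 5)
  expect_true(all(is.na(diag(cr$auc))))
  expect_true(all(cr$auc[!is.na(cr$auc)] >= 0.5))
})
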