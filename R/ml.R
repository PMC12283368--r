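#' Rank-based AUC of scores against binary labels
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney statistic
#' (ties count 0.5, via average ranks).
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Logical (or 0/1) vector; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Feature preparation for classification
#'
#' Subsets a cohort's feature space to all features, the oral-typical panel,
#' or its complement; for subsets each sample's retained abundances are
#' rescaled by their sum back onto \[0, 1\] before the arcsine-square-root
#' transform (samples with zero retained abundance stay all-zero and are
#' reported, not dropped). Output is samples x features, ready for a
#' classifier.
#'
#' @param profile A [cohort_profile()] or a features x samples matrix.
#' @param feature_set `"all"`, `"oral"`, `"nonoral"` or `"custom"`.
#' @param signature Oral signature (required for `"oral"`/`"nonoral"`).
#' @param custom_features Feature ids for `"custom"`.
#' @return Transformed samples x features matrix.
#' @export
prepare_features <- function(profile, feature_set = c("all", "oral", "nonoral", "custom"),
                             signature = NULL, custom_features = NULL) {
  feature_set <- match.arg(feature_set)
  m <- if (inherits(profile, "cohort_profile")) profile$abundances else profile
  keep <- switch(feature_set,
    all = rownames(m),
    oral = intersect(rownames(m), .signature_members(signature)),
    nonoral = setdiff(rownames(m), .signature_members(signature)),
    custom = intersect(rownames(m), custom_features))
  if (!length(keep)) stop("no features retained for feature_set = ", feature_set)
  sub <- m[keep, , drop = FALSE]
  if (feature_set != "all") {
    tot <- colSums(sub)
    zero <- tot == 0
    if (any(zero))
      message(sum(zero), " sample(s) have zero retained abundance; kept as all-zero rows")
    tot[zero] <- 1
    sub <- sweep(sub, 2L, tot, "/")
  }
  t(asin_sqrt_transform(sub))
}

#' Random-forest classifier configuration
#'
#' The default base learner of the evaluation harness: a probability forest
#' with `num_trees` trees and a minimum of `min_node_size` samples per leaf.
#' When `mtry_grid` is non-NULL, the per-split feature count is grid-searched
#' by stratified `inner_folds`-fold cross-validation on the training set only
#' (default grid: `sqrt(p)` and 10/20/30% of `p` features). Any list with
#' `fit(x, y, seed)` and `score(model, x)` entries is accepted wherever a
#' `classifier` argument appears, so the harness is classifier-agnostic.
#'
#' @param num_trees Number of trees.
#' @param min_node_size Minimum samples per leaf.
#' @param mtry_grid Numeric fractions of `p` (with `NA` meaning `sqrt(p)`), or
#'   `NULL` to use `sqrt(p)` without tuning.
#' @param inner_folds Folds of the inner tuning CV.
#' @return Classifier configuration list with `fit` and `score`.
#' @export
rf_classifier <- function(num_trees = 1000L, min_node_size = 5L,
                          mtry_grid = c(NA, 0.1, 0.2, 0.3), inner_folds = 5L) {
  fit_one <- function(x, y, mtry, seed) {
    ranger::ranger(x = x, y = factor(y, levels = c(FALSE, TRUE)),
                   num.trees = num_trees, min.node.size = min_node_size,
                   mtry = mtry, probability = TRUE, seed = seed,
                   num.threads = 1L)
  }
  score_one <- function(model, x) {
    stats::predict(model, data = x, num.threads = 1L)$predictions[, "TRUE"]
  }
  list(
    name = "random_forest",
    fit = function(x, y, seed = 1L) {
      p <- ncol(x)
      grid <- if (is.null(mtry_grid)) max(1L, floor(sqrt(p))) else
        unique(pmax(1L, pmin(p, ifelse(is.na(mtry_grid),
                                       floor(sqrt(p)), floor(mtry_grid * p)))))
      mtry <- grid[1L]
      if (length(grid) > 1L) {
        folds <- .stratified_folds(y, inner_folds, seed)
        scores <- vapply(grid, function(mt) {
          oof <- rep(NA_real_, length(y))
          for (f in seq_len(inner_folds)) {
            tr <- folds != f
            if (length(unique(y[tr])) < 2L) return(0.5)
            mod <- fit_one(x[tr, , drop = FALSE], y[tr], mt, seed + f)
            oof[!tr] <- score_one(mod, x[!tr, , drop = FALSE])
          }
          auc_rank(oof, y)
        }, numeric(1))
        mtry <- grid[which.max(scores)]
      }
      fit_one(x, y, mtry, seed)
    },
    score = score_one)
}

# stratified fold assignment: within each class, shuffled round-robin
.stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Eligibility of a cohort for classifier evaluation
#'
#' @param y Logical class vector.
#' @param min_per_class Minimum samples per class (default 15).
#' @return Logical scalar.
#' @export
cohort_eligible <- function(y, min_per_class = 15L) {
  sum(y) >= min_per_class && sum(!y) >= min_per_class
}

#' Repeated stratified cross-validation within one cohort
#'
#' 10-fold cross-validation repeated 20 times (defaults): folds are stratified
#' by class and re-randomized each repeat; per repeat the out-of-fold scores
#' are pooled into a single AUC, and the mean and standard deviation over
#' repeats are returned. Cohorts with fewer than `min_per_class` samples in
#' either class are refused.
#'
#' @param x Samples x features matrix (already transformed).
#' @param y Logical class vector (TRUE = positive class).
#' @param k Folds per repeat.
#' @param repeats Number of repeats.
#' @param min_per_class Eligibility threshold.
#' @param classifier Classifier configuration (see [rf_classifier()]).
#' @param seed Integer seed.
#' @return List with `auc` (mean), `sd`, and per-repeat AUCs.
#' @export
per_dataset_cv <- function(x, y, k = 10L, repeats = 20L, min_per_class = 15L,
                           classifier = rf_classifier(), seed = 1L) {
  y <- as.logical(y)
  if (!cohort_eligible(y, min_per_class))
    stop("cohort ineligible for CV: fewer than ", min_per_class, " samples in a class")
  rep_auc <- numeric(repeats)
  for (r in seq_len(repeats)) {
    folds <- .stratified_folds(y, k, seed + 1000L * r)
    oof <- rep(NA_real_, length(y))
    for (f in seq_len(k)) {
      tr <- folds != f
      mod <- classifier$fit(x[tr, , drop = FALSE], y[tr], seed = seed + 1000L * r + f)
      oof[!tr] <- classifier$score(mod, x[!tr, , drop = FALSE])
    }
    rep_auc[r] <- auc_rank(oof, y)
  }
  list(auc = mean(rep_auc), sd = stats::sd(rep_auc), repeat_auc = rep_auc)
}

#' Across-dataset transfer evaluation
#'
#' Trains once on one cohort and scores another; both cohorts must have at
#' least `min_per_class` samples per class. Training and test cohorts must be
#' distinct objects — use [per_dataset_cv()] for within-cohort estimates.
#'
#' @param x_train,y_train,x_test,y_test Training/test matrices and labels;
#'   matrices should carry sample ids as rownames for the leakage check.
#' @param min_per_class Eligibility threshold.
#' @param classifier Classifier configuration.
#' @param seed Integer seed.
#' @return The test AUC.
#' @export
cross_dataset <- function(x_train, y_train, x_test, y_test, min_per_class = 15L,
                          classifier = rf_classifier(), seed = 1L) {
  y_train <- as.logical(y_train); y_test <- as.logical(y_test)
  if (!cohort_eligible(y_train, min_per_class) || !cohort_eligible(y_test, min_per_class))
    stop("ineligible cohort pair: fewer than ", min_per_class, " samples in a class")
  shared <- intersect(rownames(x_train), rownames(x_test))
  if (length(shared))
    stop("training and test sets share samples: ", paste(utils::head(shared), collapse = ", "))
  mod <- classifier$fit(x_train, y_train, seed = seed)
  auc_rank(classifier$score(mod, x_test), y_test)
}

#' Leave-one-dataset-out evaluation
#'
#' Holds one cohort out entirely as the test set and trains a single model on
#' all remaining cohorts pooled. The left-out cohort must be eligible as a
#' validation set (at least `min_per_class` per class); class-unbalanced
#' cohorts may still serve in the training pool.
#'
#' @param x_list,y_list Named lists of per-cohort feature matrices (samples x
#'   features, shared feature columns) and logical label vectors.
#' @param left_out Name of the held-out cohort.
#' @param min_per_class Validation eligibility threshold.
#' @param classifier Classifier configuration.
#' @param seed Integer seed.
#' @return The left-out cohort's AUC.
#' @export
lodo <- function(x_list, y_list, left_out, min_per_class = 15L,
                 classifier = rf_classifier(), seed = 1L) {
  stopifnot(left_out %in% names(x_list))
  y_test <- as.logical(y_list[[left_out]])
  if (!cohort_eligible(y_test, min_per_class))
    stop("cohort '", left_out, "' ineligible as validation set")
  train_names <- setdiff(names(x_list), left_out)
  x_train <- do.call(rbind, x_list[train_names])
  y_train <- as.logical(unlist(y_list[train_names], use.names = FALSE))
  shared <- intersect(rownames(x_train), rownames(x_list[[left_out]]))
  if (length(shared))
    stop("left-out cohort shares samples with the training pool: ",
         paste(utils::head(shared), collapse = ", "))
  mod <- classifier$fit(x_train, y_train, seed = seed)
  auc_rank(classifier$score(mod, x_list[[left_out]]), y_test)
}

#' Full evaluation matrix across cohorts
#'
#' Runs one of the three evaluation designs over all cohorts of a study:
#' per-dataset cross-validation (`"cv"`, diagonal), all ordered train/test
#' pairs (`"cross"`), or leave-one-dataset-out (`"lodo"`). Ineligible
#' cohorts/pairs are reported as `NA` (in LODO, validation-ineligible cohorts
#' still join every training pool).
#'
#' @param profiles List of [cohort_profile()] objects.
#' @param metadata `sample_metadata` frame.
#' @param contrast Contrast string for [define_contrast()]; class 1 is the
#'   positive label.
#' @param mode `"cv"`, `"cross"` or `"lodo"`.
#' @param feature_set,signature Passed to [prepare_features()].
#' @param classifier Classifier configuration.
#' @param min_per_class Eligibility threshold (default 15).
#' @param cv_folds,cv_repeats CV design for `mode = "cv"`.
#' @param seed Integer seed.
#' @return An object of class `eval_matrix`: `auc` (matrix or named vector),
#'   `auc_sd` (cv mode), `mode`, `feature_set`.
#' @export
evaluate_transfer <- function(profiles, metadata,
                              contrast = "condition:CRC vs condition:control",
                              mode = c("cv", "cross", "lodo"),
                              feature_set = "all", signature = NULL,
                              classifier = rf_classifier(), min_per_class = 15L,
                              cv_folds = 10L, cv_repeats = 20L, seed = 1L) {
  mode <- match.arg(mode)
  sets <- define_contrast(metadata, contrast)
  x_list <- list(); y_list <- list()
  for (p in profiles) {
    ids <- intersect(p$sample_ids, c(sets$set1, sets$set2))
    if (!length(ids)) next
    xm <- prepare_features(p, feature_set, signature)[ids, , drop = FALSE]
    x_list[[p$cohort_id]] <- xm
    y_list[[p$cohort_id]] <- ids %in% sets$set1
  }
  if (length(x_list) < 1L) stop("no cohort contains samples of the contrast")
  cohorts <- names(x_list)
  eligible <- vapply(y_list, cohort_eligible, logical(1), min_per_class = min_per_class)
  if (mode == "cv") {
    auc <- sd_out <- setNames(rep(NA_real_, length(cohorts)), cohorts)
    for (cid in cohorts[eligible]) {
      res <- per_dataset_cv(x_list[[cid]], y_list[[cid]], k = cv_folds,
                            repeats = cv_repeats, min_per_class = min_per_class,
                            classifier = classifier, seed = seed)
      auc[cid] <- res$auc; sd_out[cid] <- res$sd
    }
    out <- list(auc = auc, auc_sd = sd_out)
  } else if (mode == "cross") {
    auc <- matrix(NA_real_, length(cohorts), length(cohorts),
                  dimnames = list(train = cohorts, test = cohorts))
    for (tr in cohorts[eligible]) for (te in cohorts[eligible]) {
      if (tr == te) next
      auc[tr, te] <- cross_dataset(x_list[[tr]], y_list[[tr]],
                                   x_list[[te]], y_list[[te]],
                                   min_per_class = min_per_class,
                                   classifier = classifier, seed = seed)
    }
    out <- list(auc = auc, auc_sd = NULL)
  } else {
    auc <- setNames(rep(NA_real_, length(cohorts)), cohorts)
    for (cid in cohorts[eligible])
      auc[cid] <- lodo(x_list, y_list, cid, min_per_class = min_per_class,
                       classifier = classifier, seed = seed)
    out <- list(auc = auc, auc_sd = NULL)
  }
  structure(c(out, list(mode = mode, feature_set = feature_set,
                        eligible = eligible)),
            class = "eval_matrix")
}

#' @export
print.eval_matrix <- function(x, ...) {
  cat("Evaluation (", x$mode, ", features = ", x$feature_set, "):\n", sep = "")
  print(round(x$auc, 3))
  invisible(x)
}
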