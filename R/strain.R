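#' Binary entropy of a fraction
#'
#' `H(p) = -p*log2(p) - (1-p)*log2(1-p)` in bits, with `0*log(0) = 0`.
#' Applied to major-allele frequencies of alignment columns to screen for
#' strain-level variability.
#'
#' @param p Numeric vector of fractions in \[0, 1\].
#' @return Entropy in bits.
#' @export
binary_entropy <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  term <- function(q) ifelse(q == 0, 0, -q * log2(q))
  term(p) + term(1 - p)
}

.msa_matrix <- function(msa) {
  do.call(rbind, strsplit(unname(msa$sequences), ""))
}

#' Select variable alignment columns by binary entropy
#'
#' For each column, the major-allele frequency `p` is the frequency of the
#' most common non-N symbol among non-N symbols, with the gap counted as an
#' ordinary symbol (gaps are feature levels downstream, so they contribute
#' variability). Columns with `binary_entropy(p) >= entropy_min` are kept;
#' all-N columns are dropped.
#'
#' @param msa An [msa_set()].
#' @param entropy_min Entropy threshold in bits (default 0.5).
#' @return Data frame with `position` (1-based), `major_freq` and `entropy`
#'   for the selected columns.
#' @export
select_positions <- function(msa, entropy_min = 0.5) {
  stopifnot(inherits(msa, "msa_set"))
  M <- .msa_matrix(msa)
  stats_list <- lapply(seq_len(ncol(M)), function(j) {
    col <- M[, j]
    col <- col[col != "N"]
    if (!length(col)) return(NULL)
    p <- max(table(col)) / length(col)
    data.frame(position = j, major_freq = p, entropy = binary_entropy(p))
  })
  out <- do.call(rbind, stats_list)
  if (is.null(out)) return(data.frame(position = integer(0), major_freq = numeric(0),
                                      entropy = numeric(0)))
  out[out$entropy >= entropy_min, , drop = FALSE]
}

# canonical symbol-agnostic pattern of an alignment column restricted to a
# sample subset: symbols are relabelled by order of first appearance so that
# columns inducing the same partition of samples are identical keys; N stays
# pinned (missing is not a level)
.column_pattern <- function(col) {
  syms <- unique(col[col != "N"])
  code <- match(col, syms)
  code[col == "N"] <- 0L
  paste(code, collapse = ",")
}

#' Collapse pattern-duplicate positions within sequence clusters
#'
#' De-duplicates selected columns that carry the same strain-partition
#' information. Samples are first single-linkage clustered at pairwise
#' distance (1 - identity over shared non-N columns) at most `ani_threshold`;
#' within each sample cluster, positions whose columns induce the same
#' partition of the cluster's samples (symbol-agnostic) form a duplicate
#' group, and the position with the fewest gaps in its full column is kept
#' per group. A position survives overall if it is kept in at least one
#' cluster.
#'
#' @param positions Data frame from [select_positions()] (or integer vector
#'   of 1-based positions).
#' @param msa The [msa_set()] the positions refer to.
#' @param ani_threshold Single-linkage cut height (default 0.05).
#' @return The surviving subset of `positions`, in original order.
#' @export
dedup_by_ani_clusters <- function(positions, msa, ani_threshold = 0.05) {
  pos <- if (is.data.frame(positions)) positions$position else as.integer(positions)
  if (!length(pos)) return(positions)
  M <- .msa_matrix(msa)
  n <- nrow(M)
  # pairwise 1 - identity over shared non-N columns
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- M[i, ] != "N" & M[j, ] != "N"
    D[i, j] <- D[j, i] <- if (any(ok)) mean(M[i, ok] != M[j, ok]) else 1
  }
  clust <- if (n > 1L)
    stats::cutree(stats::hclust(stats::as.dist(D), method = "single"),
                  h = ani_threshold)
  else 1L
  gap_counts <- colSums(M[, pos, drop = FALSE] == "-")
  kept <- logical(length(pos))
  for (cl in unique(clust)) {
    rows <- clust == cl
    keys <- vapply(pos, function(p) .column_pattern(M[rows, p]), character(1))
    for (grp in split(seq_along(pos), keys)) {
      best <- grp[which.min(gap_counts[grp])]
      kept[best] <- TRUE
    }
  }
  if (is.data.frame(positions)) positions[kept, , drop = FALSE] else pos[kept]
}

.symbol_levels <- c("A", "C", "G", "T", "gap")

#' One-hot encode alignment columns into binary strain features
#'
#' Each selected position expands into five features — one per nucleotide and
#' one for the gap. A sample scores 1 on the feature matching its residue and
#' 0 elsewhere; an `N` residue (missing) scores 0 on all five. Feature ids
#' are stable strings `"<sgb>:<position>:<symbol>"`.
#'
#' @param msa An [msa_set()].
#' @param positions Data frame from [select_positions()] or integer vector.
#' @return An object of class `strain_features`: binary `values` (samples x
#'   features), a `feature_info` frame (sgb, position, symbol), `provenance`.
#' @export
one_hot_encode <- function(msa, positions) {
  pos <- if (is.data.frame(positions)) positions$position else as.integer(positions)
  M <- .msa_matrix(msa)
  stopifnot(all(pos >= 1L), all(pos <= ncol(M)))
  n <- nrow(M)
  vals <- matrix(0L, n, 5L * length(pos))
  info <- data.frame(sgb_id = character(0), position = integer(0), symbol = character(0))
  if (length(pos)) {
    info <- data.frame(sgb_id = msa$sgb_id,
                       position = rep(pos, each = 5L),
                       symbol = rep(.symbol_levels, length(pos)),
                       stringsAsFactors = FALSE)
    for (k in seq_along(pos)) {
      col <- M[, pos[k]]
      for (s in 1:5) {
        sym <- c("A", "C", "G", "T", "-")[s]
        vals[, 5L * (k - 1L) + s] <- as.integer(col == sym)
      }
    }
  }
  dimnames(vals) <- list(msa$sample_ids,
                         if (nrow(info)) sprintf("%s:%d:%s", info$sgb_id,
                                                 info$position, info$symbol))
  structure(list(values = vals, feature_info = info,
                 provenance = list()),
            class = "strain_features")
}

#' @export
print.strain_features <- function(x, ...) {
  cat("Strain feature matrix: ", nrow(x$values), " samples x ",
      ncol(x$values), " binary features\n", sep = "")
  invisible(x)
}

.subset_strain <- function(sf, keep) {
  sf$values <- sf$values[, keep, drop = FALSE]
  sf$feature_info <- sf$feature_info[keep, , drop = FALSE]
  rownames(sf$feature_info) <- NULL
  sf
}

#' Prevalence filter for binary strain features
#'
#' Removes base-preference features that are very rare or near-universal:
#' features with pooled control+CRC prevalence below `low` or above `high`
#' are dropped (both bounds inclusive for keeping, since the removal rules
#' are strict `<20%` / `>80%`).
#'
#' @param sf A `strain_features` object.
#' @param keep_samples Optional sample ids restricting the prevalence
#'   computation to the control+CRC subset; all samples by default.
#' @param low,high Prevalence band (defaults 0.20 and 0.80).
#' @return Filtered `strain_features`.
#' @export
prevalence_filter <- function(sf, keep_samples = NULL, low = 0.20, high = 0.80) {
  stopifnot(inherits(sf, "strain_features"))
  m <- sf$values
  if (!is.null(keep_samples)) m <- m[rownames(m) %in% keep_samples, , drop = FALSE]
  prev <- colMeans(m)
  out <- .subset_strain(sf, prev >= low & prev <= high)
  out$provenance$prevalence <- c(low = low, high = high)
  out
}

# phi coefficient (Pearson r of two binary vectors) from the 2x2 table
.phi <- function(x, y) {
  n <- length(x)
  n11 <- sum(x & y); n10 <- sum(x & !y); n01 <- sum(!x & y); n00 <- n - n11 - n10 - n01
  den <- sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
  if (den == 0) return(NA_real_)
  (n11 * n00 - n10 * n01) / den
}

#' Greedy collinearity pruning of binary features
#'
#' Walks features in construction order and keeps a feature only if its
#' absolute Pearson correlation (phi coefficient, computed exactly from the
#' 2x2 table) with every previously kept feature is at most `r_max`. Constant
#' features (zero variance) are dropped first with a warning.
#'
#' @param sf A `strain_features` object.
#' @param r_max Correlation threshold (default 0.5; features correlated
#'   strictly above it with an earlier representative are discarded).
#' @return Pruned `strain_features`.
#' @export
collinearity_prune <- function(sf, r_max = 0.5) {
  stopifnot(inherits(sf, "strain_features"))
  m <- sf$values
  constant <- apply(m, 2L, function(v) length(unique(v)) < 2L)
  if (any(constant)) {
    warning(sum(constant), " constant feature(s) dropped before pruning")
    sf <- .subset_strain(sf, !constant)
    m <- sf$values
  }
  p <- ncol(m)
  if (p <= 1L) return(sf)
  kept <- integer(0)
  for (j in seq_len(p)) {
    ok <- TRUE
    for (i in kept) {
      r <- .phi(m[, i] == 1L, m[, j] == 1L)
      if (!is.na(r) && abs(r) > r_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, j)
  }
  out <- .subset_strain(sf, kept)
  out$provenance$r_max <- r_max
  out
}

#' Full strain-feature pipeline for one species alignment
#'
#' Chains entropy-based position selection, optional cluster-aware pattern
#' de-duplication, one-hot encoding, prevalence filtering and greedy
#' collinearity pruning, logging the feature-count funnel at each stage.
#'
#' @param msa An [msa_set()].
#' @param entropy_min Entropy threshold in bits.
#' @param ani_dedup Apply [dedup_by_ani_clusters()] (default `TRUE`).
#' @param ani_threshold Cluster cut height.
#' @param keep_samples,prev_low,prev_high Passed to [prevalence_filter()].
#' @param r_max Passed to [collinearity_prune()].
#' @return A `strain_features` object whose `provenance$funnel` records the
#'   feature counts after each stage.
#' @export
strain_feature_pipeline <- function(msa, entropy_min = 0.5, ani_dedup = TRUE,
                                    ani_threshold = 0.05, keep_samples = NULL,
                                    prev_low = 0.20, prev_high = 0.80,
                                    r_max = 0.5) {
  pos <- select_positions(msa, entropy_min)
  funnel <- c(positions_selected = nrow(pos))
  if (ani_dedup) {
    pos <- dedup_by_ani_clusters(pos, msa, ani_threshold)
    funnel <- c(funnel, positions_deduplicated = nrow(pos))
  }
  sf <- one_hot_encode(msa, pos)
  funnel <- c(funnel, one_hot = ncol(sf$values))
  sf <- prevalence_filter(sf, keep_samples, prev_low, prev_high)
  funnel <- c(funnel, prevalence = ncol(sf$values))
  sf <- suppressWarnings(collinearity_prune(sf, r_max))
  funnel <- c(funnel, pruned = ncol(sf$values))
  sf$provenance$entropy_min <- entropy_min
  sf$provenance$funnel <- funnel
  sf
}

#' Blocked PERMANOVA on strain features with Jaccard distance
#'
#' Computes Jaccard distances between samples' binary strain profiles and
#' runs [permanova_blocked()]. Samples with all-zero feature rows have no
#' defined Jaccard distance and are excluded with a warning.
#'
#' @param sf A `strain_features` object (or binary samples x features matrix).
#' @param labels Group factor aligned to the matrix rows.
#' @param blocks Block (cohort) factor.
#' @param n_perm,seed Passed to [permanova_blocked()].
#' @return A `permanova_result`.
#' @export
strain_permanova <- function(sf, labels, blocks = NULL, n_perm = 999L, seed = 1L) {
  m <- if (inherits(sf, "strain_features")) sf$values else sf
  keep <- rowSums(m) > 0
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) with all-zero strain profiles excluded")
    m <- m[keep, , drop = FALSE]
    labels <- labels[keep]
    if (!is.null(blocks)) blocks <- blocks[keep]
  }
  d <- sample_distances(m, "jaccard")
  permanova_blocked(d, labels, blocks, n_perm = n_perm, seed = seed)
}
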