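#' Shannon diversity index of a sample
#'
#' Positive abundances are renormalized to sum 1 and the index is
#' `H = -sum(p * log(p))`, in nats (natural log, matching vegan's default).
#'
#' @param sample Nonnegative numeric vector with at least one positive entry.
#' @return Shannon index in nats.
#' @export
shannon_index <- function(sample) {
  if (any(sample < 0, na.rm = TRUE)) stop("abundances must be nonnegative")
  pos <- sample[!is.na(sample) & sample > 0]
  if (!length(pos)) stop("all-zero sample has no defined Shannon index")
  as.numeric(vegan::diversity(pos, index = "shannon"))
}

#' Species richness of a sample
#'
#' @param sample Numeric abundance vector.
#' @param threshold Entries strictly above this count as present.
#' @return Integer count.
#' @export
richness <- function(sample, threshold = 0) {
  sum(sample > threshold, na.rm = TRUE)
}

#' Bray-Curtis dissimilarity between two samples
#'
#' `sum(|a - b|) / sum(a + b)` over a shared feature order.
#'
#' @param a,b Nonnegative numeric vectors of equal length.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (any(a < 0) || any(b < 0)) stop("abundances must be nonnegative")
  tot <- sum(a + b)
  if (tot == 0) stop("Bray-Curtis undefined for two all-zero samples")
  sum(abs(a - b)) / tot
}

#' Pairwise distance matrix for a set of samples
#'
#' Thin wrapper over [vegan::vegdist()] producing the matrices consumed by
#' [permanova_blocked()]: Bray-Curtis on relative abundances or Jaccard on
#' binary (presence) profiles.
#'
#' @param x Samples x features numeric matrix.
#' @param method `"braycurtis"` or `"jaccard"` (binary).
#' @return A symmetric `dist` object.
#' @export
sample_distances <- function(x, method = c("braycurtis", "jaccard")) {
  method <- match.arg(method)
  switch(method,
         braycurtis = vegan::vegdist(x, method = "bray"),
         jaccard = vegan::vegdist(x > 0, method = "jaccard", binary = TRUE))
}

.permanova_f <- function(D2, labels) {
  N <- nrow(D2)
  a <- nlevels(labels)
  ss_total <- sum(D2[upper.tri(D2)]) / N
  ss_within <- 0
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    if (length(idx) > 1L)
      ss_within <- ss_within + sum(D2[idx, idx][upper.tri(D2[idx, idx])]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  f <- (ss_between / (a - 1)) / (ss_within / (N - a))
  c(f = f, r2 = ss_between / ss_total)
}

#' PERMANOVA with permutations restricted to blocks
#'
#' One-factor permutational multivariate analysis of variance on a distance
#' matrix, with the permutation null built by shuffling group labels
#' independently *within* each block (here: within each cohort), so that
#' cohort-level batch structure is held fixed. Sums of squares follow the
#' standard decomposition (`SS_total = sum(d^2)/N`; within-group sums divided
#' by group size), `R2 = SS_between / SS_total`, and
#' `pseudo-F = (SS_between/(a-1)) / (SS_within/(N-a))`. The p-value uses the
#' add-one correction `(1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#'
#' @param d A `dist` object or symmetric matrix with zero diagonal.
#' @param labels Group factor (at least two levels present).
#' @param blocks Block factor (e.g. cohort); a single level reduces to the
#'   unrestricted test.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return An object of class `permanova_result` with `r2`, `pseudo_f`, `p`,
#'   `n_perm` and the block sizes used.
#' @export
permanova_blocked <- function(d, labels, blocks = NULL, n_perm = 999L, seed = 1L) {
  D <- as.matrix(d)
  N <- nrow(D)
  if (any(abs(diag(D)) > 1e-12) || any(abs(D - t(D)) > 1e-8))
    stop("distance matrix must be symmetric with zero diagonal")
  labels <- droplevels(as.factor(labels))
  if (length(labels) != N) stop("labels must align with the distance matrix")
  if (nlevels(labels) < 2L) stop("PERMANOVA needs at least two groups")
  if (is.null(blocks)) blocks <- rep(1L, N)
  blocks <- as.factor(blocks)
  if (length(blocks) != N) stop("blocks must align with the distance matrix")
  one_sample_blocks <- names(which(table(blocks) == 1L))
  if (length(one_sample_blocks))
    warning("block(s) with a single sample cannot be permuted: ",
            paste(one_sample_blocks, collapse = ", "))
  D2 <- D^2
  obs <- .permanova_f(D2, labels)
  block_idx <- split(seq_len(N), blocks)
  set.seed(seed)
  count <- 0L
  perm_labels <- labels
  for (b in seq_len(n_perm)) {
    for (idx in block_idx)
      perm_labels[idx] <- labels[idx][sample.int(length(idx))]
    if (.permanova_f(D2, perm_labels)[["f"]] >= obs[["f"]]) count <- count + 1L
  }
  structure(list(r2 = unname(obs[["r2"]]), pseudo_f = unname(obs[["f"]]),
                 p = (1 + count) / (1 + n_perm), n_perm = as.integer(n_perm),
                 blocks = table(blocks)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("Blocked PERMANOVA: R2 = %.4f, pseudo-F = %.3f, p = %.4g (%d permutations, %d block(s))\n",
              x$r2, x$pseudo_f, x$p, x$n_perm, length(x$blocks)))
  invisible(x)
}

#' Per-sample diversity and oral-introgression summary table
#'
#' Computes Shannon diversity, richness, and (when a signature is given) the
#' oral-to-gut score and richness for every sample of the supplied profiles.
#'
#' @param profiles List of [cohort_profile()] objects.
#' @param signature Optional oral signature for the introgression scores.
#' @return A data frame with one row per sample.
#' @export
diversity_table <- function(profiles, signature = NULL) {
  do.call(rbind, lapply(profiles, function(p) {
    out <- data.frame(
      sample_id = p$sample_ids, cohort_id = p$cohort_id,
      shannon = apply(p$abundances, 2L, shannon_index),
      richness = apply(p$abundances, 2L, richness),
      stringsAsFactors = FALSE)
    if (!is.null(signature)) {
      out$oral_score <- apply(p$abundances, 2L, oral_to_gut_score, signature = signature)
      out$oral_richness <- apply(p$abundances, 2L, oral_to_gut_richness, signature = signature)
    }
    rownames(out) <- NULL
    out
  }))
}
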