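# small in-code fixtures shared across test files

tiny_profile <- function(cohort_id = "c1", n_feat = 6L, n_samp = 4L, seed = 1L) {
  set.seed(seed)
  m <- matrix(stats::runif(n_feat * n_samp), n_feat, n_samp)
  m <- sweep(m, 2L, colSums(m) * 1.2, "/")   # column sums < 1
  dimnames(m) <- list(sprintf("SGB%03d", seq_len(n_feat)),
                      sprintf("%s_s%d", cohort_id, seq_len(n_samp)))
  cohort_profile(cohort_id, m)
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# brute-force two-sided Fisher p by enumerating all tables with fixed margins,
# table probabilities from products of binomial coefficients
fisher_enum_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  xs <- max(0, k - n):min(k, m)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exhaustive within-block PERMANOVA p: enumerate all distinct within-block
# label arrangements and count pseudo-F >= observed
permanova_exhaustive_p <- function(D, labels, blocks) {
  D2 <- as.matrix(D)^2
  f_stat <- function(lab) {
    lab <- factor(lab)
    N <- nrow(D2); a <- nlevels(lab)
    ss_t <- sum(D2[upper.tri(D2)]) / N
    ss_w <- 0
    for (lv in levels(lab)) {
      idx <- which(lab == lv)
      if (length(idx) > 1)
        ss_w <- ss_w + sum(D2[idx, idx][upper.tri(D2[idx, idx])]) / length(idx)
    }
    ((ss_t - ss_w) / (a - 1)) / (ss_w / (N - a))
  }
  obs <- f_stat(labels)
  block_idx <- split(seq_along(labels), blocks)
  perms_of <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  arrangements <- lapply(block_idx, function(idx) perms_of(as.character(labels[idx])))
  grid <- expand.grid(lapply(arrangements, seq_along))
  fs <- apply(grid, 1L, function(row) {
    lab <- as.character(labels)
    for (bi in seq_along(block_idx))
      lab[block_idx[[bi]]] <- arrangements[[bi]][[row[bi]]]
    f_stat(lab)
  })
  mean(fs >= obs - 1e-12)
}
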