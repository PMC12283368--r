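msa_from <- function(...) {
  seqs <- c(...)
  names(seqs) <- sprintf("s%02d", seq_along(seqs))
  msa_set("sgbT", seqs)
}

test_that("binary entropy matches its closed form at the threshold boundary", {
  expect_equal(binary_entropy(0.5), 1)
  expect_equal(binary_entropy(0), 0)
  expect_equal(binary_entropy(1), 0)
  expect_equal(binary_entropy(0.11), -0.11 * log2(0.11) - 0.89 * log2(0.89))
  expect_lt(binary_entropy(0.11), 0.5)       # just below the selection threshold
  expect_equal(binary_entropy(0.89), binary_entropy(0.11))  # symmetric
  expect_gt(binary_entropy(0.15), 0.5)
})

test_that("position selection screens by major-allele entropy with gap as symbol", {
  # column 1 invariant; column 2 50/50 biallelic; column 3 gap-vs-base 50/50
  msa <- msa_from("AAG", "AC-", "AAG", "AC-")
  sel <- select_positions(msa)
  expect_setequal(sel$position, c(2L, 3L))
  expect_true(all(sel$major_freq == 0.5))

  # 89/11 excluded, 85/15 included (entropy ~0.61); N ignored in frequencies
  col89 <- c(rep("A", 89), rep("C", 11))
  col85 <- c(rep("A", 85), rep("C", 15))
  seqs <- paste0(col89, col85)
  msa2 <- msa_set("sgb2", setNames(seqs, sprintf("s%03d", 1:100)))
  sel2 <- select_positions(msa2)
  expect_identical(sel2$position, 2L)

  # all-N columns are dropped entirely
  msa3 <- msa_from("NA", "NC", "NA", "NC")
  expect_identical(select_positions(msa3)$position, 2L)
})

test_that("pattern de-duplication keeps the least-gapped representative", {
  # duplicate-pattern fixture within one cluster: columns 1 and 2 induce the
  # same sample partition with different symbols; the gapped one loses
  seqs <- c("AG", "AG", "C-", "C-")   # col1 partition {12}{34} = col2 partition; col2 has 2 gaps
  msa2 <- msa_set("sgbD", setNames(seqs, sprintf("s%d", 1:4)))
  kept2 <- dedup_by_ani_clusters(data.frame(position = 1:2), msa2, ani_threshold = 1.1)
  expect_identical(kept2$position, 1L)   # fewer gaps wins

  # all patterns distinct -> all kept
  msa3 <- msa_set("sgbE", setNames(c("AA", "AC", "CA", "CC"), sprintf("s%d", 1:4)))
  kept3 <- dedup_by_ani_clusters(data.frame(position = 1:2), msa3, ani_threshold = 1.1)
  expect_identical(kept3$position, 1:2)
})

test_that("one-hot encoding conserves exactly one symbol per non-N residue", {
  msa <- msa_from("A-N", "CGT")
  sf <- one_hot_encode(msa, 1:3)
  expect_equal(ncol(sf$values), 15L)
  expect_equal(unname(sf$values["s01", c("sgbT:1:A", "sgbT:1:C", "sgbT:1:G",
                                         "sgbT:1:T", "sgbT:1:gap")]),
               c(1L, 0L, 0L, 0L, 0L))
  expect_equal(unname(sf$values["s01", "sgbT:2:gap"]), 1L)
  # N residue contributes zero across all five features of position 3
  expect_equal(sum(sf$values["s01", sprintf("sgbT:3:%s", c("A","C","G","T","gap"))]), 0L)
  # conservation: total ones per sample = number of non-N selected positions
  expect_equal(unname(rowSums(sf$values)), c(2L, 3L))
})

test_that("prevalence band keeps [0.2, 0.8] inclusively", {
  vals <- cbind(all_on = rep(1L, 10),
                half = rep(c(1L, 0L), 5),
                rare = c(1L, rep(0L, 9)),
                at20 = c(rep(1L, 2), rep(0L, 8)),
                at80 = c(rep(1L, 8), rep(0L, 2)))
  rownames(vals) <- sprintf("s%d", 1:10)
  sf <- structure(list(values = vals,
                       feature_info = data.frame(sgb_id = "x", position = 1:5,
                                                 symbol = "A"),
                       provenance = list()), class = "strain_features")
  out <- prevalence_filter(sf)
  expect_setequal(colnames(out$values), c("half", "at20", "at80"))
})

test_that("greedy collinearity pruning follows construction order", {
  base <- rep(c(1L, 0L), 8)
  vals <- cbind(f1 = base, f2 = base, f3 = 1L - base, f4 = rep(c(1L, 1L, 0L, 0L), 4))
  rownames(vals) <- sprintf("s%d", 1:16)
  sf <- structure(list(values = vals,
                       feature_info = data.frame(sgb_id = "x", position = 1:4,
                                                 symbol = "A"),
                       provenance = list()), class = "strain_features")
  out <- collinearity_prune(sf)
  # duplicate (r = 1) and complement (r = -1) both pruned; f4 orthogonal kept
  expect_setequal(colnames(out$values), c("f1", "f4"))

  # constant features dropped with a warning before pruning
  sf$values <- cbind(sf$values, konst = rep(1L, 16))
  sf$feature_info <- rbind(sf$feature_info,
                           data.frame(sgb_id = "x", position = 5, symbol = "A"))
  expect_warning(out2 <- collinearity_prune(sf), "constant")
  expect_false("konst" %in% colnames(out2$values))
})

test_that("the pipeline funnel is monotone and conserves one-hot structure", {
  gen <- generate_msa(60, 120, n_clades = 2, divergence = 0.02, gap_rate = 0.02,
                      seed = 19)
  sf <- strain_feature_pipeline(gen$msa)
  funnel <- sf$provenance$funnel
  expect_true(all(diff(funnel[c("one_hot", "prevalence", "pruned")]) <= 0))
  expect_equal(unname(funnel[["one_hot"]]),
               5L * unname(funnel[["positions_deduplicated"]]))
  expect_true(all(sf$values %in% c(0L, 1L)))
  # switch off de-duplication: pass-through of selected positions
  sf_nd <- strain_feature_pipeline(gen$msa, ani_dedup = FALSE)
  expect_equal(unname(sf_nd$provenance$funnel[["one_hot"]]),
               5L * unname(sf_nd$provenance$funnel[["positions_selected"]]))
})

test_that("strain PERMANOVA separates clade-aligned labels; single block = unblocked", {
  gen <- generate_msa(70, 140, n_clades = 2, divergence = 0.01, gap_rate = 0.02,
                      seed = 29)
  sf <- strain_feature_pipeline(gen$msa)
  labs <- factor(c("control", "CRC"))[gen$clades]
  aligned <- suppressWarnings(strain_permanova(sf, labs, n_perm = 499, seed = 2))
  expect_lte(aligned$p, 0.01)
  un <- suppressWarnings(strain_permanova(sf, labs, blocks = rep(1, 70),
                                          n_perm = 499, seed = 2))
  expect_equal(aligned$p, un$p)
  expect_equal(aligned$r2, un$r2)
})
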