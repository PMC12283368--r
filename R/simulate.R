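#' Configuration for the synthetic multi-cohort generator
#'
#' Bundles the study-design parameters the generator emulates: number of
#' cohorts, per-class sample sizes, feature panel size, planted case-control
#' effects (on the Hedges' g scale of arcsine-square-root abundances),
#' oral-feature introgression in CRC, monotone stage trends, and per-cohort
#' batch offsets.
#'
#' @param n_cohorts Number of cohorts.
#' @param samples_per_class Named integer vector, counts per cohort for each
#'   condition; names drawn from `control`, `adenoma`, `CRC`.
#' @param n_features Number of features (SGBs).
#' @param n_oral_features How many features are flagged oral-typical; these are
#'   the first `n_oral_features` feature ids.
#' @param planted_effects Named numeric vector mapping feature ids to target
#'   standardized mean differences (positive = higher in CRC). Features not
#'   named carry no effect.
#' @param oral_introgression_boost Multiplicative abundance enrichment of oral
#'   features in CRC samples (1 = none).
#' @param stage_trend_features Character vector of features given a monotone
#'   abundance gradient across CRC stages 0-IV.
#' @param stage_trend_g Standardized mean difference between stage 0 and stage
#'   IV for stage-trend features.
#' @param cohort_batch_sd Standard deviation of per-cohort, per-feature
#'   log-scale offsets (the batch effect).
#' @param within_sd Within-group log-scale standard deviation.
#' @param prevalence Fraction of samples in which a feature is detected; the
#'   smallest values per feature and cohort are zeroed to reach it.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cohorts = 5L,
                       samples_per_class = c(control = 100L, CRC = 100L),
                       n_features = 200L,
                       n_oral_features = 40L,
                       planted_effects = numeric(0),
                       oral_introgression_boost = 1,
                       stage_trend_features = character(0),
                       stage_trend_g = 0.5,
                       cohort_batch_sd = 0.5,
                       within_sd = 1,
                       prevalence = 0.9,
                       seed = 1L) {
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              samples_per_class = samples_per_class,
              n_features = as.integer(n_features),
              n_oral_features = as.integer(n_oral_features),
              planted_effects = planted_effects,
              oral_introgression_boost = oral_introgression_boost,
              stage_trend_features = as.character(stage_trend_features),
              stage_trend_g = stage_trend_g,
              cohort_batch_sd = cohort_batch_sd,
              within_sd = within_sd,
              prevalence = prevalence,
              seed = as.integer(seed))
  if (cfg$n_cohorts < 1L || cfg$n_features < 1L || any(samples_per_class < 1L))
    stop("all counts must be positive")
  if (cfg$n_oral_features > cfg$n_features)
    stop("n_oral_features cannot exceed n_features")
  if (is.null(names(samples_per_class)) ||
      !all(names(samples_per_class) %in% c("control", "adenoma", "CRC")))
    stop("samples_per_class must be named with condition levels")
  if (length(planted_effects) && is.null(names(planted_effects)))
    stop("planted_effects must be named by feature id")
  if (length(planted_effects) > cfg$n_features)
    stop("more planted effects than features")
  class(cfg) <- "sim_config"
  cfg
}

.sim_feature_ids <- function(cfg) sprintf("SGB%04d", seq_len(cfg$n_features))

# Closed-form calibration: within each group log-abundance is normal with sd
# `s`, so sqrt(abundance) is log-normal with sdlog s/2 and coefficient of
# variation kappa = sqrt(exp(s^2/4) - 1). A log-scale shift delta multiplies
# the mean of sqrt(abundance) by r = exp(delta/2), and (using the small-p
# approximation asin(sqrt(p)) ~ sqrt(p)) the standardized mean difference is
#   g = (r - 1) / (kappa * sqrt((r^2 + 1) / 2)).
# Solving for r given a target g yields the quadratic below; delta = 2 log r.
.g_to_delta <- function(g, within_sd) {
  if (g == 0) return(0)
  kappa <- sqrt(exp(within_sd^2 / 4) - 1)
  a <- g^2 * kappa^2 / 2
  if (a >= 1)
    stop("target effect size ", g, " not attainable at within_sd = ", within_sd)
  r <- (1 + sign(g) * sqrt(a * (2 - a))) / (1 - a)
  2 * log(r)
}

.stage_probs <- c("0" = 0.08, "I" = 0.21, "II" = 0.22, "III" = 0.24, "IV" = 0.25)

#' Generate a synthetic multi-cohort case-control study
#'
#' Draws, per cohort, log-normal latent abundances with per-cohort batch
#' offsets, applies class, oral-introgression and stage-trend effects on the
#' log scale (calibrated by a documented closed-form mapping so that the
#' realized per-cohort Hedges' g of arcsine-square-root abundances
#' approximates the planted values), closes each sample to sum 1, and then
#' introduces zeros by per-feature prevalence thresholding.
#'
#' @param config A [sim_config()].
#' @return A list with `profiles` (list of [cohort_profile()]), `metadata`
#'   (one `sample_metadata` frame covering all cohorts) and `ground_truth`
#'   (planted g per feature, oral membership, stage-trend membership).
#' @export
generate_multicohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  feats <- .sim_feature_ids(config)
  oral <- feats[seq_len(config$n_oral_features)]
  planted <- setNames(numeric(length(feats)), feats)
  if (length(config$planted_effects)) {
    unknown <- setdiff(names(config$planted_effects), feats)
    if (length(unknown)) stop("planted effect on unknown feature(s): ",
                              paste(unknown, collapse = ", "))
    planted[names(config$planted_effects)] <- config$planted_effects
  }
  delta <- vapply(planted, .g_to_delta, numeric(1), within_sd = config$within_sd)
  boost_delta <- log(config$oral_introgression_boost)
  stage_delta <- .g_to_delta(config$stage_trend_g, config$within_sd)

  base_mu <- stats::rnorm(length(feats), 0, 1.5)   # heavy-tailed feature means
  classes <- rep(names(config$samples_per_class), config$samples_per_class)

  profiles <- vector("list", config$n_cohorts)
  meta <- vector("list", config$n_cohorts)
  for (ci in seq_len(config$n_cohorts)) {
    cid <- sprintf("cohort%02d", ci)
    n <- length(classes)
    sids <- sprintf("%s_s%03d", cid, seq_len(n))
    batch <- stats::rnorm(length(feats), 0, config$cohort_batch_sd)
    is_crc <- classes == "CRC"
    stage <- rep("unknown", n)
    location <- rep("unknown", n)
    if (any(is_crc)) {
      stage[is_crc] <- sample(names(.stage_probs), sum(is_crc), TRUE, .stage_probs)
      location[is_crc] <- sample(c("right", "left"), sum(is_crc), TRUE, c(0.35, 0.65))
    }
    # stage rank 0..1 drives the monotone trend; non-CRC samples sit at 0
    stage_rank <- ifelse(is_crc, (match(stage, c("0", "I", "II", "III", "IV")) - 1) / 4, 0)

    shift <- matrix(0, length(feats), n, dimnames = list(feats, sids))
    shift[, is_crc] <- shift[, is_crc] + delta
    if (boost_delta != 0)
      shift[oral, is_crc] <- shift[oral, is_crc] + boost_delta
    if (length(config$stage_trend_features))
      shift[config$stage_trend_features, ] <-
        shift[config$stage_trend_features, ] +
        rep(stage_rank * stage_delta, each = length(config$stage_trend_features))

    eps <- matrix(stats::rnorm(length(feats) * n, 0, config$within_sd),
                  length(feats), n)
    latent <- exp(base_mu + batch + shift + eps)
    ab <- sweep(latent, 2L, colSums(latent), "/")
    if (config$prevalence < 1) {
      n_zero <- floor((1 - config$prevalence) * n)
      if (n_zero > 0L)
        for (f in seq_len(nrow(ab)))
          ab[f, order(ab[f, ])[seq_len(n_zero)]] <- 0
    }
    dimnames(ab) <- list(feats, sids)
    profiles[[ci]] <- cohort_profile(cid, ab)
    meta[[ci]] <- sample_metadata(
      sample_id = sids, cohort_id = cid, condition = classes,
      stage = stage, location = location,
      age = round(pmin(pmax(stats::rnorm(n, 62, 11), 25), 90), 1),
      sex = sample(c("female", "male"), n, TRUE),
      bmi = round(pmin(pmax(stats::rnorm(n, 26, 4), 15), 45), 1))
  }
  metadata <- do.call(rbind, lapply(meta, as.data.frame))
  class(metadata) <- c("sample_metadata", "data.frame")
  list(profiles = profiles,
       metadata = metadata,
       ground_truth = list(planted_g = planted,
                           oral_features = oral,
                           stage_trend_features = config$stage_trend_features))
}

#' Default body-site tropism probabilities for paired-sample simulation
#'
#' Generates per-SGB probabilities of the mutually exclusive detection
#' patterns (oral-only, both sites, stool-only) for a paired oral-stool
#' cohort. Tropism in real paired cohorts is strongly bimodal — most species
#' are either clearly oral-typical or clearly gut-resident — so the default is
#' a two-component mixture: a fraction `p_oral_typical` of SGBs with high
#' oral-only prevalence and near-zero stool-only prevalence, the rest with low
#' oral-only prevalence and a broad range of gut patterns.
#'
#' @param n_sgbs Number of SGBs.
#' @param p_oral_typical Mixture weight of the oral-typical component.
#' @return Matrix `n_sgbs` x 3 with columns `oral_only`, `both`, `stool_only`
#'   and SGB ids as rownames.
#' @export
bodysite_truth <- function(n_sgbs = 300L, p_oral_typical = 0.2) {
  ids <- sprintf("SGB%04d", seq_len(n_sgbs))
  is_oral <- stats::runif(n_sgbs) < p_oral_typical
  oral_only <- ifelse(is_oral, stats::runif(n_sgbs, 0.28, 0.70),
                      stats::runif(n_sgbs, 0, 0.12))
  both <- ifelse(is_oral, stats::runif(n_sgbs, 0, 0.6) * oral_only,
                 stats::runif(n_sgbs, 0, 0.25))
  stool_only <- ifelse(is_oral, stats::runif(n_sgbs, 0, 0.03),
                       stats::runif(n_sgbs, 0, 0.5))
  tr <- cbind(oral_only = oral_only, both = both, stool_only = stool_only)
  tr <- tr / pmax(1, rowSums(tr) + 1e-9)   # keep pattern probabilities feasible
  rownames(tr) <- ids
  tr
}

#' Simulate a paired oral-stool presence cohort
#'
#' Each participant contributes one oral and one stool sample; for each SGB
#' the detection pattern (oral-only / both / stool-only / neither) is drawn
#' from the SGB's true pattern probabilities. The true oral-typical signature
#' is computed from the probabilities themselves with the three derivation
#' criteria, so recovery by [derive_oral_signature()] can be scored.
#'
#' @param n_participants Number of participants with both body sites.
#' @param truth Per-SGB pattern probability matrix as from [bodysite_truth()];
#'   generated with the defaults when `NULL`.
#' @param seed Integer seed.
#' @return List with 0/1 matrices `oral` and `stool` (participants x SGBs),
#'   the `truth` matrix and `true_signature` (character vector).
#' @export
generate_paired_bodysites <- function(n_participants = 495L, truth = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(truth)) truth <- bodysite_truth()
  stopifnot(is.matrix(truth), ncol(truth) == 3L, !is.null(rownames(truth)))
  if (any(truth < 0) || any(rowSums(truth) > 1 + 1e-9))
    stop("pattern probabilities must be nonnegative and sum to at most 1 per SGB")
  n_sgbs <- nrow(truth)
  oral <- stool <- matrix(0L, n_participants, n_sgbs,
                          dimnames = list(sprintf("p%03d", seq_len(n_participants)),
                                          rownames(truth)))
  for (j in seq_len(n_sgbs)) {
    u <- stats::runif(n_participants)
    p <- truth[j, ]
    pat <- findInterval(u, cumsum(c(p[1], p[2], p[3]))) # 0=oral_only,1=both,2=stool_only,3=neither
    oral[, j] <- as.integer(pat <= 1L)
    stool[, j] <- as.integer(pat == 1L | pat == 2L)
  }
  true_sig <- rownames(truth)[truth[, "oral_only"] >= 0.20 &
                                truth[, "both"] < truth[, "oral_only"] &
                                truth[, "stool_only"] < 0.05]
  list(oral = oral, stool = stool, truth = truth, true_signature = true_sig)
}

#' Simulate a clade-structured marker-gene alignment
#'
#' Builds a random consensus sequence, plants clade-discriminating columns
#' (each clade gets a distinct symbol there), then copies the clade consensus
#' to each sample with independent per-position substitutions, gaps and
#' missing calls.
#'
#' @param n_samples Number of sequences.
#' @param n_positions Alignment length.
#' @param n_clades Number of clades.
#' @param clade_assignments Optional integer vector (length `n_samples`,
#'   values in `1:n_clades`); balanced round-robin when `NULL`.
#' @param divergence Per-position probability of a random substitution.
#' @param gap_rate Per-position probability of a gap.
#' @param missing_rate Per-position probability of an `N` call.
#' @param n_discriminating Number of clade-discriminating columns (default 10%
#'   of positions; forced to 0 when `n_clades == 1`).
#' @param discriminating_noise Probability that a sample carries another
#'   clade's symbol at a discriminating column. Real marker-gene clades are
#'   only partially concordant across positions; a nonzero rate (default 0.2)
#'   keeps one-hot features informative about clades without making them
#'   perfectly collinear with each other.
#' @param seed Integer seed.
#' @return List with `msa` (an [msa_set()]), `clades` (integer vector) and
#'   `discriminating_positions` (1-based column indices).
#' @export
generate_msa <- function(n_samples, n_positions, n_clades = 2L,
                         clade_assignments = NULL, divergence = 0.005,
                         gap_rate = 0.01, missing_rate = 0,
                         n_discriminating = max(1L, round(0.1 * n_positions)),
                         discriminating_noise = 0.2, seed = 1L) {
  stopifnot(n_samples >= 1L, n_positions >= 1L, n_clades >= 1L)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  if (is.null(clade_assignments))
    clade_assignments <- rep_len(seq_len(n_clades), n_samples)
  stopifnot(length(clade_assignments) == n_samples,
            all(clade_assignments %in% seq_len(n_clades)))
  if (n_clades == 1L) n_discriminating <- 0L
  root <- sample(bases, n_positions, TRUE)
  disc <- sort(sample.int(n_positions, min(n_discriminating, n_positions)))
  consensus <- matrix(rep(root, n_clades), n_clades, n_positions, byrow = TRUE)
  for (k in seq_len(n_clades))
    consensus[k, disc] <- bases[((match(root[disc], bases) - 1L + (k - 1L)) %% 4L) + 1L]
  seqs <- character(n_samples)
  for (i in seq_len(n_samples)) {
    ch <- consensus[clade_assignments[i], ]
    if (n_clades > 1L && discriminating_noise > 0 && length(disc)) {
      flip <- disc[stats::runif(length(disc)) < discriminating_noise]
      for (p in flip) {
        other <- setdiff(seq_len(n_clades), clade_assignments[i])
        ch[p] <- consensus[if (length(other) == 1L) other else sample(other, 1L), p]
      }
    }
    mut <- stats::runif(n_positions) < divergence
    if (any(mut))
      ch[mut] <- vapply(ch[mut], function(b) sample(setdiff(bases, b), 1L), character(1))
    ch[stats::runif(n_positions) < gap_rate] <- "-"
    if (missing_rate > 0)
      ch[stats::runif(n_positions) < missing_rate] <- "N"
    seqs[i] <- paste(ch, collapse = "")
  }
  names(seqs) <- sprintf("s%03d", seq_len(n_samples))
  list(msa = msa_set("SGBsim", seqs),
       clades = clade_assignments,
       discriminating_positions = disc)
}
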