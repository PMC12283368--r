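#' Derive the oral-typical species signature from paired body-site presence
#'
#' Given presence/absence of each SGB in the oral cavity and stool of the same
#' participants, an SGB enters the oral-typical panel when, across
#' participants with both body sites sampled:
#' (1) it is present exclusively in the oral cavity of at least
#'     `min_oral_only` (default 20%) of participants;
#' (2) it is found in both body sites in fewer participants than exclusively
#'     in the oral cavity; and
#' (3) it is present exclusively in stool in fewer than `max_stool_only`
#'     (default 5%) of participants.
#' All three fractions share the same denominator: the number of participants
#' with both samples.
#'
#' @param oral,stool 0/1 matrices, participants x SGBs, aligned rows. SGBs
#'   absent from one matrix are treated as absent at that body site.
#' @param min_oral_only Criterion (1) threshold, inclusive.
#' @param max_stool_only Criterion (3) threshold, exclusive.
#' @return An object of class `oral_signature` with `members`, a `stats` data
#'   frame of the three per-SGB fractions, and the thresholds used.
#' @export
derive_oral_signature <- function(oral, stool, min_oral_only = 0.20,
                                  max_stool_only = 0.05) {
  stopifnot(is.matrix(oral), is.matrix(stool))
  if (nrow(oral) != nrow(stool)) stop("oral and stool must cover the same participants")
  n <- nrow(oral)
  if (n < 1L) stop("at least one participant with both body sites is required")
  sgbs <- union(colnames(oral), colnames(stool))
  if (is.null(sgbs)) stop("presence matrices must have SGB column names")
  pad <- function(m) {
    out <- matrix(0L, n, length(sgbs), dimnames = list(rownames(m), sgbs))
    out[, colnames(m)] <- (m > 0) + 0L
    out
  }
  o <- pad(oral); s <- pad(stool)
  frac_oral_only <- colSums(o == 1L & s == 0L) / n
  frac_both <- colSums(o == 1L & s == 1L) / n
  frac_stool_only <- colSums(o == 0L & s == 1L) / n
  keep <- frac_oral_only >= min_oral_only &
    frac_both < frac_oral_only &
    frac_stool_only < max_stool_only
  structure(list(
    members = sgbs[keep],
    stats = data.frame(sgb_id = sgbs,
                       frac_oral_only = unname(frac_oral_only),
                       frac_both = unname(frac_both),
                       frac_stool_only = unname(frac_stool_only),
                       member = unname(keep),
                       row.names = NULL),
    thresholds = c(min_oral_only = min_oral_only, max_stool_only = max_stool_only),
    n_participants = n),
    class = "oral_signature")
}

#' @export
print.oral_signature <- function(x, ...) {
  cat("Oral-typical signature: ", length(x$members), " of ", nrow(x$stats),
      " SGBs (", x$n_participants, " paired participants)\n", sep = "")
  invisible(x)
}

.signature_members <- function(signature) {
  if (inherits(signature, "oral_signature")) signature$members
  else if (inherits(signature, "signature_set")) signature$members
  else as.character(signature)
}

#' Oral-to-gut score of a stool sample
#'
#' Sums the relative abundance of the oral-typical SGBs present in a stool
#' sample — a per-sample measure of oral-to-gut introgression. Signature
#' members missing from the sample's feature space contribute zero.
#'
#' @param sample Named numeric vector of relative abundances in \[0, 1\].
#' @param signature An `oral_signature`, [signature_set()] or character vector
#'   of feature ids.
#' @return The summed abundance, in \[0, 1\].
#' @export
oral_to_gut_score <- function(sample, signature) {
  members <- .signature_members(signature)
  sum(sample[names(sample) %in% members])
}

#' Oral-to-gut richness of a stool sample
#'
#' Counts the distinct oral-typical SGBs detected in a stool sample.
#'
#' @inheritParams oral_to_gut_score
#' @param detection_threshold Abundance strictly above this counts as present.
#' @return Integer count.
#' @export
oral_to_gut_richness <- function(sample, signature, detection_threshold = 0) {
  members <- .signature_members(signature)
  sum(sample[names(sample) %in% members] > detection_threshold)
}

#' Two-sided Fisher exact test for signature enrichment
#'
#' Tests whether signature membership is enriched in one feature set versus
#' another (e.g. oral-typical SGBs among CRC-positive biomarkers vs among
#' non-significant features) from the 2x2 table
#' `rbind(c(a, b), c(c, d))` = (signature/non-signature) x (set A/set B).
#' The two-sided p-value sums hypergeometric probabilities of all tables with
#' the observed margins that are no more probable than the observed table.
#' The odds ratio is the sample odds ratio `(a*d)/(b*c)`, `Inf` when
#' `b*c == 0` with `a*d > 0`, and undefined (NA, flagged) when a margin is
#' zero, in which case `p = 1`.
#'
#' @param table 2x2 integer matrix of nonnegative counts.
#' @return List with `odds_ratio`, `p`, and `undefined` flag.
#' @export
enrichment_fisher <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(odds_ratio = NA_real_, p = 1, undefined = TRUE))
  m <- a + c; nn <- b + d; k <- a + b
  x_all <- max(0L, k - nn):min(k, m)
  dens <- stats::dhyper(x_all, m, nn, k)
  p <- sum(dens[dens <= stats::dhyper(a, m, nn, k) * (1 + 1e-7)])
  or <- if (b * c == 0) { if (a * d == 0) NA_real_ else Inf } else (a * d) / (b * c)
  list(odds_ratio = or, p = min(1, p), undefined = FALSE)
}
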