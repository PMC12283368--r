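#' Construct a cohort abundance profile
#'
#' A cohort profile holds one cohort's feature-by-sample relative-abundance
#' matrix (unitless fractions in \[0, 1\]) together with the cohort identifier.
#' Rows are species-level genome bins (SGBs) or other taxonomic/functional
#' features; columns are samples.
#'
#' @param cohort_id Single string identifying the cohort.
#' @param abundances Numeric matrix, features x samples, with unique rownames
#'   (feature identifiers) and colnames (sample identifiers). Values must lie
#'   in \[0, 1\] and each column must sum to at most 1 (plus a small numeric
#'   tolerance).
#' @return An object of class `cohort_profile`.
#' @export
cohort_profile <- function(cohort_id, abundances) {
  stopifnot(is.character(cohort_id), length(cohort_id) == 1L,
            is.matrix(abundances), is.numeric(abundances))
  if (is.null(rownames(abundances)) || is.null(colnames(abundances)))
    stop("abundances must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(abundances)))
    stop("duplicate feature identifiers in abundance matrix")
  if (anyDuplicated(colnames(abundances)))
    stop("duplicate sample identifiers in abundance matrix")
  if (anyNA(abundances) || any(abundances < 0) || any(abundances > 1 + 1e-9))
    stop("abundances must be fractions in [0, 1]")
  cs <- colSums(abundances)
  if (any(cs > 1 + 1e-6))
    stop("sample column sums exceed 1: ", paste(colnames(abundances)[cs > 1 + 1e-6], collapse = ", "))
  structure(list(cohort_id = cohort_id,
                 feature_ids = rownames(abundances),
                 sample_ids = colnames(abundances),
                 abundances = abundances),
            class = "cohort_profile")
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat("Cohort profile '", x$cohort_id, "': ", length(x$feature_ids),
      " features x ", length(x$sample_ids), " samples\n", sep = "")
  invisible(x)
}

#' Read a merged relative-abundance table
#'
#' Reads a MetaPhlAn-style merged TSV (first column = feature identifiers,
#' remaining columns = numeric abundances per sample). Tables given as
#' percentages (0-100) are auto-detected (any column sum > 1.5) and divided by
#' 100 so that downstream code always works on fractions in \[0, 1\].
#' Lines starting with `#` are ignored.
#'
#' @param path Path to a tab-delimited file.
#' @param cohort_id Cohort identifier attached to the profile; defaults to the
#'   file name without extension.
#' @return A [cohort_profile()].
#' @export
read_abundance_table <- function(path, cohort_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(cohort_id))
    cohort_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("abundance table needs a feature column and at least one sample column")
  feats <- raw[[1L]]
  if (anyDuplicated(feats))
    stop("duplicate feature id(s): ", paste(unique(feats[duplicated(feats)]), collapse = ", "))
  mat <- matrix(NA_real_, nrow(raw), ncol(raw) - 1L,
                dimnames = list(feats, colnames(raw)[-1L]))
  for (j in seq_len(ncol(mat))) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(v) & !is.na(raw[[j + 1L]]) & raw[[j + 1L]] != "NA")
    if (length(bad))
      stop("malformed numeric cell at row '", feats[bad[1L]], "', column '",
           colnames(raw)[j + 1L], "': ", raw[[j + 1L]][bad[1L]])
    mat[, j] <- v
  }
  if (any(colSums(mat) > 1.5)) mat <- mat / 100
  cohort_profile(cohort_id, mat)
}

#' Write a cohort profile as a merged TSV
#'
#' Emits a tab-delimited table readable by [read_abundance_table()]. Numeric
#' output uses 15 significant digits, making write/read round trips lossless
#' to well below 1e-12 and byte-stable for fixed input.
#'
#' @param profile A [cohort_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(profile, path) {
  stopifnot(inherits(profile, "cohort_profile"))
  m <- profile$abundances
  lines <- c(paste(c("feature_id", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], sprintf("%.15g", m[i, ])), collapse = "\t"),
               character(1L)))
  writeLines(lines, path)
  invisible(path)
}

.condition_levels <- c("control", "adenoma", "CRC")
.stage_levels <- c("0", "I", "II", "III", "IV", "unknown")
.location_levels <- c("right", "left", "unknown")
.sex_levels <- c("female", "male", "missing")
.in_situ_levels <- c("yes", "no", "not_applicable")

#' Construct per-sample clinical metadata
#'
#' Builds the validated metadata table used throughout the package. Optional
#' covariates default to explicit missing/unknown sentinels; nothing is imputed
#' at this layer. Tumor stage (TNM/AJCC 0-IV) and primary tumor location
#' (right = cecum/ascending/transverse colon, left = descending/sigmoid/rectum)
#' are only meaningful for CRC samples, and the constructor enforces that.
#'
#' @param sample_id,cohort_id Character vectors.
#' @param condition One of `"control"`, `"adenoma"`, `"CRC"` per sample.
#' @param stage Stage label in `c("0","I","II","III","IV","unknown")`.
#' @param location `"right"`, `"left"` or `"unknown"`.
#' @param age,bmi Numeric; `NA` for missing.
#' @param sex `"female"`, `"male"` or `"missing"`.
#' @param primary_tumor_in_situ `"yes"`, `"no"` or `"not_applicable"`.
#' @return A `data.frame` of class `sample_metadata`.
#' @export
sample_metadata <- function(sample_id, cohort_id, condition,
                            stage = "unknown", location = "unknown",
                            age = NA_real_, sex = "missing", bmi = NA_real_,
                            primary_tumor_in_situ = "not_applicable") {
  n <- length(sample_id)
  df <- data.frame(
    sample_id = as.character(sample_id),
    cohort_id = rep_len(as.character(cohort_id), n),
    condition = factor(rep_len(as.character(condition), n), .condition_levels),
    stage = factor(rep_len(as.character(stage), n), .stage_levels),
    location = factor(rep_len(as.character(location), n), .location_levels),
    age = rep_len(as.numeric(age), n),
    sex = factor(rep_len(as.character(sex), n), .sex_levels),
    bmi = rep_len(as.numeric(bmi), n),
    primary_tumor_in_situ = factor(rep_len(as.character(primary_tumor_in_situ), n),
                                   .in_situ_levels),
    stringsAsFactors = FALSE)
  if (anyNA(df$condition)) stop("invalid condition value(s)")
  if (anyNA(df$stage)) stop("invalid stage value(s)")
  if (anyNA(df$location)) stop("invalid location value(s)")
  bad <- df$stage != "unknown" & df$condition != "CRC"
  if (any(bad))
    stop("stage given for non-CRC sample(s): ", paste(df$sample_id[bad], collapse = ", "))
  bad <- df$location != "unknown" & df$condition != "CRC"
  if (any(bad))
    stop("location given for non-CRC sample(s): ", paste(df$sample_id[bad], collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id(s)")
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read a per-sample metadata TSV
#'
#' Required columns: `sample_id`, `cohort_id`, `condition`. Optional columns
#' `stage`, `location`, `age`, `sex`, `bmi`, `primary_tumor_in_situ` default to
#' the missing/unknown sentinel when absent or empty.
#'
#' @param path Path to a tab-delimited file (`#` comment lines ignored).
#' @return A `sample_metadata` data frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "cohort_id", "condition")
  miss <- setdiff(need, colnames(raw))
  if (length(miss)) stop("metadata is missing required column(s): ", paste(miss, collapse = ", "))
  opt <- function(col, default) {
    if (!col %in% colnames(raw)) return(rep(default, nrow(raw)))
    v <- raw[[col]]
    v[is.na(v) | v == ""] <- default
    v
  }
  sample_metadata(
    sample_id = raw$sample_id, cohort_id = raw$cohort_id, condition = raw$condition,
    stage = opt("stage", "unknown"), location = opt("location", "unknown"),
    age = suppressWarnings(as.numeric(opt("age", NA))),
    sex = opt("sex", "missing"),
    bmi = suppressWarnings(as.numeric(opt("bmi", NA))),
    primary_tumor_in_situ = opt("primary_tumor_in_situ", "not_applicable"))
}

#' Write sample metadata as TSV
#' @param metadata A `sample_metadata` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  df <- as.data.frame(metadata)
  df$age <- ifelse(is.na(df$age), "", sprintf("%.15g", df$age))
  df$bmi <- ifelse(is.na(df$bmi), "", sprintf("%.15g", df$bmi))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a multiple-sequence-alignment set
#'
#' Holds a per-SGB marker-gene alignment: equal-length sequences over the
#' alphabet `{A, C, G, T, -, N}`. Lower-case input is upper-cased; any other
#' symbol (e.g. IUPAC ambiguity codes) is mapped to `N`, i.e. treated as
#' missing at that position, with a warning reporting the substitution count.
#'
#' @param sgb_id Single string naming the SGB.
#' @param sequences Named character vector of aligned sequences.
#' @return An object of class `msa_set` with fields `sgb_id`, `sample_ids`,
#'   `sequences` and `length` (number of alignment columns).
#' @export
msa_set <- function(sgb_id, sequences) {
  stopifnot(is.character(sequences), length(sequences) >= 1L)
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    stop("sequences must be named by sample identifiers")
  if (anyDuplicated(names(sequences))) stop("duplicate sample identifiers in MSA")
  sequences <- toupper(sequences)
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L)
    stop("aligned sequences must all have the same length")
  n_sub <- sum(vapply(strsplit(sequences, ""), function(ch)
    sum(!ch %in% c("A", "C", "G", "T", "-", "N")), integer(1L)))
  if (n_sub > 0L) {
    sequences <- vapply(strsplit(sequences, ""), function(ch) {
      ch[!ch %in% c("A", "C", "G", "T", "-", "N")] <- "N"
      paste(ch, collapse = "")
    }, character(1L), USE.NAMES = TRUE)
    names(sequences) <- names(widths)
    warning(n_sub, " symbol(s) outside {A,C,G,T,-,N} mapped to N")
  }
  structure(list(sgb_id = sgb_id, sample_ids = names(sequences),
                 sequences = sequences, length = unname(widths[1L])),
            class = "msa_set")
}

#' @export
print.msa_set <- function(x, ...) {
  cat("MSA '", x$sgb_id, "': ", length(x$sample_ids), " sequences x ",
      x$length, " columns\n", sep = "")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned multi-FASTA.
#' @param sgb_id SGB identifier; defaults to the file name without extension.
#' @return An [msa_set()].
#' @export
read_msa <- function(path, sgb_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sgb_id)) sgb_id <- sub("\\.[^.]*$", "", basename(path))
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  msa_set(sgb_id, seqs)
}

#' Write an MSA as aligned FASTA
#' @param msa An [msa_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  stopifnot(inherits(msa, "msa_set"))
  writeLines(as.vector(rbind(paste0(">", msa$sample_ids), unname(msa$sequences))), path)
  invisible(path)
}

#' Construct a named feature-identifier set
#'
#' Signature sets hold biomarker panels (stage signatures, disease signatures,
#' the oral-typical panel, cardiometabolic panels) for overlap analytics.
#'
#' @param name Set name.
#' @param members Character vector of feature identifiers (deduplicated).
#' @param provenance Free-text description of how the set was derived.
#' @return An object of class `signature_set`.
#' @export
signature_set <- function(name, members, provenance = "") {
  structure(list(name = name, members = unique(as.character(members)),
                 provenance = provenance),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("Signature '", x$name, "': ", length(x$members), " members\n", sep = "")
  invisible(x)
}
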