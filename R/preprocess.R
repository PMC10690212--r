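# Data preprocessing: coefficient-of-variation filtering, covariate
# regression, centering/scaling, and subject alignment across blocks.

# Coefficient of variation per column: sample sd / |mean|. Columns with mean
# exactly 0 get +Inf (variability is defined, the ratio is not; such features
# survive any finite threshold).
cov_values <- function(x) {
  m <- colMeans(x)
  s <- apply(x, 2L, stats::sd)
  cv <- ifelse(m == 0, Inf, s / abs(m))
  cv[s == 0 & m != 0] <- 0
  cv
}

#' Filter features by coefficient of variation
#'
#' Keeps features whose coefficient of variation (sample standard deviation
#' divided by the absolute mean) is at least `threshold`, preserving column
#' order. Features with mean exactly 0 are retained (with a warning) since
#' the ratio is undefined but the feature is not degenerate; constant
#' features (sd 0, mean nonzero) have CoV 0 and are removed by any positive
#' threshold.
#'
#' @param x numeric matrix, subjects x features, with column names.
#' @param threshold nonnegative CoV cutoff.
#' @param label block label used in messages.
#' @return the filtered matrix.
#' @export
filter_by_cov <- function(x, threshold, label = "block") {
  x <- as.matrix(x)
  if (ncol(x) < 1L) stop2("block '%s' has no features", label)
  if (threshold < 0) stop2("threshold must be >= 0")
  cv <- cov_values(x)
  if (any(is.infinite(cv)))
    warn2("block '%s': %d feature(s) with mean 0 retained (CoV undefined)",
          label, sum(is.infinite(cv)))
  keep <- cv >= threshold
  if (!any(keep))
    stop2("empty block: CoV filter at threshold %g removed every feature of block '%s'",
          threshold, label)
  dropped <- sum(!keep)
  if (dropped > 0)
    msg("block '%s': CoV filter dropped %d of %d features", label, dropped, ncol(x))
  x[, keep, drop = FALSE]
}

#' Regress covariates out of every feature
#'
#' Replaces each feature column by its residuals from an ordinary least
#' squares fit on the covariates plus an intercept. Run before
#' [center_scale()] so that scaling restores unit variance afterwards.
#'
#' @param x numeric matrix, subjects x features.
#' @param covariates numeric matrix or data.frame, subjects x covariates, in
#'   the same row order as `x` (checked via rownames when both are named).
#' @return matrix of residuals with the dimensions and dimnames of `x`.
#' @export
regress_out_covariates <- function(x, covariates) {
  x <- as.matrix(x)
  if (!is.data.frame(covariates)) {
    covariates <- as.matrix(covariates)
    zero <- apply(covariates, 2L, function(v) all(v == 0))
    if (any(zero)) {
      msg("dropping %d all-zero covariate column(s); fit reduces to the intercept",
          sum(zero))
      covariates <- covariates[, !zero, drop = FALSE]
    }
  }
  cv <- if (is.data.frame(covariates)) {
    stats::model.matrix(~ ., data = covariates)
  } else {
    cbind(`(Intercept)` = 1, covariates)
  }
  if (nrow(cv) != nrow(x))
    stop2("covariates have %d rows but block has %d subjects", nrow(cv), nrow(x))
  if (!is.null(rownames(x)) && !is.null(rownames(covariates)) &&
      !identical(rownames(x), rownames(covariates)))
    stop2("subject identifiers differ between block and covariates")
  qr_d <- qr(cv)
  if (qr_d$rank < ncol(cv))
    stop2("covariate design is rank-deficient (rank %d < %d columns)",
          qr_d$rank, ncol(cv))
  res <- qr.resid(qr_d, x)
  dimnames(res) <- dimnames(x)
  res
}

#' Center and scale every feature
#'
#' Standardizes each column to mean 0, sample standard deviation 1.
#'
#' @param x numeric matrix, subjects x features.
#' @return the standardized matrix.
#' @export
center_scale <- function(x) {
  x <- as.matrix(x)
  s <- apply(x, 2L, stats::sd)
  if (any(s == 0)) {
    bad <- colnames(x)[s == 0] %||% which(s == 0)
    stop2("constant column(s) cannot be scaled: %s (run filter_by_cov first)",
          paste(utils::head(bad, 5L), collapse = ", "))
  }
  out <- scale(x, center = TRUE, scale = s)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Align omics blocks and phenotype on common subjects
#'
#' Restricts every block and the phenotype to the intersection of their
#' subjects, using the subject order of the first block. Input row order is
#' irrelevant; rownames (blocks) and names (phenotype) identify subjects.
#'
#' @param blocks named list of matrices with subject rownames.
#' @param phenotype vector named by subject identifiers.
#' @param modality passed to [multiomics_dataset()].
#' @return a `multiomics` dataset on the common subjects.
#' @export
align_dataset <- function(blocks, phenotype, modality = NULL) {
  if (is.null(names(phenotype)))
    stop2("phenotype must be named by subject identifiers")
  for (i in seq_along(blocks))
    if (is.null(rownames(blocks[[i]])))
      stop2("every block needs subject rownames")
  common <- rownames(blocks[[1L]])
  for (b in blocks) common <- intersect(common, rownames(b))
  common <- intersect(common, names(phenotype))
  if (length(common) == 0L)
    stop2("no subjects are shared by all blocks and the phenotype")
  dropped <- length(union(names(phenotype),
                          unique(unlist(lapply(blocks, rownames))))) - length(common)
  if (dropped > 0)
    msg("alignment dropped %d subject(s) absent from some input", dropped)
  blocks <- lapply(blocks, function(b) b[common, , drop = FALSE])
  multiomics_dataset(blocks, phenotype[common], modality = modality)
}

#' Full preprocessing of one omics block
#'
#' Applies, in order: coefficient-of-variation filtering (optional),
#' covariate regression (optional), centering and scaling.
#'
#' @param x numeric matrix, subjects x features.
#' @param cov_threshold CoV cutoff, or `NULL` to skip filtering. There is no
#'   universally sensible default; choose per platform.
#' @param covariates optional covariate matrix/data.frame to regress out.
#' @param label block label used in messages.
#' @return the preprocessed matrix.
#' @export
preprocess_block <- function(x, cov_threshold = NULL, covariates = NULL,
                             label = "block") {
  if (anyNA(x)) stop2("block '%s' contains missing values", label)
  if (!is.null(cov_threshold)) x <- filter_by_cov(x, cov_threshold, label)
  if (!is.null(covariates)) x <- regress_out_covariates(x, covariates)
  center_scale(x)
}

#' Read a delimited subjects-by-features matrix
#'
#' Expects a header row of feature names and a first column of subject
#' identifiers; the delimiter is auto-detected by [data.table::fread()].
#'
#' @param path file path.
#' @return numeric matrix with subject rownames.
#' @export
read_omics_matrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2L) stop2("'%s': need a subject column plus >=1 feature", path)
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(dt[[1L]])
  msg("read %s: %d subjects x %d features", basename(path), nrow(m), ncol(m))
  m
}

#' Write a matrix as TSV with a subject/feature id column
#'
#' @param x matrix with rownames.
#' @param path output file.
#' @param id_name name of the identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path, id_name = "id") {
  df <- data.frame(rownames(x) %||% seq_len(nrow(x)), x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_name
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
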