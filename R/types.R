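# Core containers: the aligned multi-omics dataset, scaling schemes and
# penalty specifications consumed by the solvers.

#' Assemble an aligned multi-omics dataset
#'
#' Bundles one or more omics blocks (subjects x features matrices sharing row
#' order) with a phenotype into the container every downstream stage consumes.
#' Subjects must already be aligned; use [align_dataset()] to intersect and
#' reorder blocks whose subjects differ.
#'
#' @param blocks named list of numeric matrices (subjects x features) with
#'   identical rownames (subject identifiers) in identical order and unique
#'   column names per block.
#' @param phenotype numeric vector (quantitative) or a vector with exactly two
#'   distinct values (binary); length `nrow(blocks[[1]])`. For binary
#'   phenotypes the lexicographically smaller label is coded 0.
#' @param modality `"quantitative"`, `"binary"`, or `NULL` to detect from the
#'   phenotype: exactly two distinct values means binary (a message is emitted
#'   when a numeric 0/1 vector is auto-detected as binary; pass
#'   `modality = "quantitative"` to override).
#' @return An object of class `multiomics`, a list with elements `blocks`,
#'   `subjects`, `phenotype` (numeric; 0/1 for binary), `modality`, and
#'   `pheno_labels` (original binary labels or `NULL`).
#' @export
multiomics_dataset <- function(blocks, phenotype, modality = NULL) {
  if (!is.list(blocks) || length(blocks) < 1L)
    stop2("`blocks` must be a non-empty list of matrices")
  if (is.null(names(blocks)) || any(!nzchar(names(blocks))))
    names(blocks) <- paste0("block", seq_along(blocks))
  blocks <- lapply(blocks, function(b) {
    b <- as.matrix(b)
    storage.mode(b) <- "double"
    b
  })
  n <- nrow(blocks[[1L]])
  subjects <- rownames(blocks[[1L]])
  if (is.null(subjects)) subjects <- as.character(seq_len(n))
  for (lab in names(blocks)) {
    b <- blocks[[lab]]
    if (nrow(b) != n)
      stop2("block '%s' has %d rows; expected %d", lab, nrow(b), n)
    rn <- rownames(b) %||% as.character(seq_len(nrow(b)))
    if (!identical(rn, subjects))
      stop2("block '%s' subjects differ from the first block; run align_dataset()", lab)
    if (is.null(colnames(b)))
      colnames(blocks[[lab]]) <- paste0(lab, "_", seq_len(ncol(b)))
    if (anyDuplicated(colnames(blocks[[lab]])))
      stop2("block '%s' has duplicated feature names", lab)
    if (anyNA(b))
      stop2("block '%s' contains missing values; impute or drop before use", lab)
  }
  if (length(phenotype) != n)
    stop2("phenotype length %d does not match %d subjects", length(phenotype), n)
  if (anyNA(phenotype)) stop2("phenotype contains missing values")

  distinct <- unique(phenotype)
  if (is.null(modality)) {
    if (length(distinct) < 2L)
      stop2("phenotype has a single distinct value")
    if (length(distinct) == 2L) {
      modality <- "binary"
      if (is.numeric(phenotype))
        msg("numeric phenotype with 2 distinct values treated as binary; pass modality = 'quantitative' to override")
    } else {
      if (!is.numeric(phenotype))
        stop2("non-numeric phenotype with %d distinct values; binary phenotypes need exactly 2", length(distinct))
      modality <- "quantitative"
    }
  }
  modality <- match.arg(modality, c("quantitative", "binary"))
  pheno_labels <- NULL
  if (modality == "binary") {
    if (length(distinct) != 2L)
      stop2("binary phenotype must have exactly 2 distinct values, found %d", length(distinct))
    labs <- sort(as.character(distinct))          # smaller label coded 0
    values <- as.numeric(as.character(phenotype) == labs[2L])
    pheno_labels <- labs
  } else {
    if (!is.numeric(phenotype)) stop2("quantitative phenotype must be numeric")
    values <- as.numeric(phenotype)
  }
  structure(
    list(blocks = blocks, subjects = subjects, phenotype = values,
         modality = modality, pheno_labels = pheno_labels),
    class = "multiomics"
  )
}

#' @export
print.multiomics <- function(x, ...) {
  cat(sprintf("multiomics dataset: %d subjects, %d block(s), %s phenotype\n",
              length(x$subjects), length(x$blocks), x$modality))
  for (lab in names(x$blocks))
    cat(sprintf("  %s: %d features\n", lab, ncol(x$blocks[[lab]])))
  invisible(x)
}

n_subjects <- function(data) length(data$subjects)

block_sizes <- function(data) vapply(data$blocks, ncol, integer(1))

#' Restrict a dataset to a subset of subjects
#'
#' @param data a `multiomics` dataset.
#' @param idx integer or logical subject index.
#' @return a `multiomics` dataset on the selected subjects.
#' @export
subset_subjects <- function(data, idx) {
  blocks <- lapply(data$blocks, function(b) b[idx, , drop = FALSE])
  out <- data
  out$blocks <- blocks
  out$subjects <- data$subjects[idx]
  out$phenotype <- data$phenotype[idx]
  out
}

#' Restrict a dataset to per-block feature subsets
#'
#' @param data a `multiomics` dataset.
#' @param feature_idx named list (one entry per block) of column indices.
#' @return a `multiomics` dataset on the selected features.
#' @export
subset_features <- function(data, feature_idx) {
  stopifnot(identical(names(feature_idx), names(data$blocks)))
  out <- data
  out$blocks <- Map(function(b, j) b[, j, drop = FALSE], data$blocks, feature_idx)
  out
}

# Concatenate blocks column-wise with block-prefixed feature names; returns
# the matrix plus a (block, feature) index used by similarity/pruning stages.
concat_blocks <- function(data) {
  labs <- names(data$blocks)
  mats <- lapply(labs, function(l) {
    b <- data$blocks[[l]]
    colnames(b) <- paste(l, colnames(b), sep = ":")
    b
  })
  x <- do.call(cbind, mats)
  index <- data.frame(
    block = rep(labs, times = block_sizes(data)),
    feature = unlist(lapply(data$blocks, colnames), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  rownames(index) <- colnames(x)
  list(x = x, index = index)
}

#' Scaling scheme for the multiple-CCA objective
#'
#' Nonnegative multipliers weighting each between-omics correlation term
#' (`between[i, j]`) and each omics-phenotype term (`pheno[i]`) in the sparse
#' multiple CCA objective.
#'
#' @param between symmetric numeric matrix (blocks x blocks, dimnames = block
#'   labels) of nonnegative between-omics factors; the diagonal is ignored.
#' @param pheno named nonnegative numeric vector of omics-phenotype factors,
#'   one per block.
#' @return an object of class `scaling_scheme`.
#' @export
scaling_scheme <- function(between, pheno) {
  between <- as.matrix(between)
  if (nrow(between) != ncol(between)) stop2("`between` must be square")
  if (any(between < 0) || any(pheno < 0)) stop2("scaling factors must be >= 0")
  if (max(abs(between - t(between))) > 1e-12) stop2("`between` must be symmetric")
  labs <- rownames(between) %||% names(pheno)
  if (is.null(labs)) stop2("scaling scheme needs block labels as dimnames/names")
  dimnames(between) <- list(labs, labs)
  diag(between) <- 0
  pheno <- stats::setNames(as.numeric(pheno), labs)
  if (all(between == 0) && all(pheno == 0))
    stop2("at least one scaling factor must be positive")
  structure(list(between = between, pheno = pheno), class = "scaling_scheme")
}

#' Unweighted scaling scheme (all factors one)
#'
#' @param labels character vector of block labels.
#' @param include_phenotype if `FALSE`, phenotype factors are 0.
#' @return a `scaling_scheme`.
#' @export
uniform_scaling <- function(labels, include_phenotype = TRUE) {
  T <- length(labels)
  between <- matrix(1, T, T, dimnames = list(labels, labels))
  diag(between) <- 0
  scaling_scheme(between, stats::setNames(rep(if (include_phenotype) 1 else 0, T), labels))
}

# Per-block sparsity fractions l_t in (0, 1]; mapped to the LASSO bound
# c_t = max(1, l_t * sqrt(p_t)) so grids are comparable across block widths.
check_penalties <- function(penalties, labels) {
  if (length(penalties) == 1L) penalties <- rep(penalties, length(labels))
  if (length(penalties) != length(labels))
    stop2("need one penalty per block (%d), got %d", length(labels), length(penalties))
  if (any(penalties <= 0 | penalties > 1))
    stop2("penalties must lie in (0, 1]")
  stats::setNames(as.numeric(penalties), labels)
}

penalty_to_bound <- function(l, p) max(1, l * sqrt(p))
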