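# Synthetic multi-omics generator with planted cross-block latent structure,
# so every pipeline stage is testable without external downloads.

#' Specification for a synthetic multi-omics dataset
#'
#' The generator draws one shared Gaussian latent factor; planted features
#' in every block load on it (`loading * factor + N(0, noise_sd)`), the
#' remaining features are independent standard normal background, and the
#' phenotype is `effect * factor + N(0, noise_sd)` (quantitative) or
#' Bernoulli with `plogis(effect * factor + binary_offset)` (binary).
#'
#' @param n number of subjects (default 200).
#' @param p per-block feature counts (default two blocks of 100).
#' @param planted per-block planted feature counts (default 5 each; planted
#'   features occupy the leading columns).
#' @param loading latent-factor loading strength of planted features
#'   (default 1).
#' @param effect phenotype effect size of the factor (default 1).
#' @param noise_sd noise standard deviation for planted features and the
#'   quantitative phenotype (default 0.3).
#' @param modality `"quantitative"` (default) or `"binary"`.
#' @param binary_offset logit intercept for binary mixing (default 0, i.e.
#'   balanced classes).
#' @param seed integer seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n = 200L, p = c(100L, 100L), planted = c(5L, 5L),
                           loading = 1, effect = 1, noise_sd = 0.3,
                           modality = c("quantitative", "binary"),
                           binary_offset = 0, seed = 1L) {
  modality <- match.arg(modality)
  if (length(planted) != length(p)) stop2("planted and p lengths differ")
  if (any(planted > p)) stop2("planted set sizes cannot exceed block sizes")
  if (any(planted < 0) || any(p < 1)) stop2("invalid block/planted sizes")
  if (noise_sd < 0) stop2("noise_sd must be >= 0")
  if (n < 4L) stop2("need at least 4 subjects")
  structure(list(n = n, p = p, planted = planted, loading = loading,
                 effect = effect, noise_sd = noise_sd, modality = modality,
                 binary_offset = binary_offset, seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic multi-omics dataset
#'
#' @param spec a [synthetic_spec()].
#' @return list with `data` (a `multiomics` dataset), `truth` (list with
#'   `factor`, the latent values, and `planted`, per-block planted feature
#'   names), and `spec`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n
    z <- stats::rnorm(n)
    labs <- paste0("omics", seq_along(spec$p))
    subjects <- sprintf("S%03d", seq_len(n))
    blocks <- vector("list", length(spec$p))
    planted_names <- vector("list", length(spec$p))
    for (t in seq_along(spec$p)) {
      p <- spec$p[t]
      k <- spec$planted[t]
      x <- matrix(stats::rnorm(n * p), n, p)
      if (k > 0)
        x[, seq_len(k)] <- spec$loading * z +
          matrix(stats::rnorm(n * k, sd = spec$noise_sd), n, k)
      colnames(x) <- sprintf("%s_f%03d", labs[t], seq_len(p))
      rownames(x) <- subjects
      blocks[[t]] <- x
      planted_names[[t]] <- colnames(x)[seq_len(k)]
    }
    names(blocks) <- names(planted_names) <- labs
    phenotype <- if (spec$modality == "quantitative") {
      spec$effect * z + stats::rnorm(n, sd = spec$noise_sd)
    } else {
      pr <- stats::plogis(spec$effect * z + spec$binary_offset)
      lab <- stats::rbinom(n, 1L, pr)
      if (length(unique(lab)) < 2L) lab[which.max(z)] <- 1 - lab[which.max(z)]
      c("control", "case")[lab + 1L]
    }
    names(phenotype) <- subjects
    data <- multiomics_dataset(blocks, phenotype,
                               modality = spec$modality)
    list(data = data, truth = list(factor = z, planted = planted_names),
         spec = spec)
  })
}

#' Write a synthetic dataset to delimited files
#'
#' One TSV per block, one phenotype TSV, and a ground-truth TSV naming the
#' planted features.
#'
#' @param gen a [generate_synthetic()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(gen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (lab in names(gen$data$blocks))
    write_matrix_tsv(gen$data$blocks[[lab]],
                     file.path(dir, paste0(lab, ".tsv")), id_name = "subject")
  ph <- data.frame(subject = gen$data$subjects, phenotype = gen$data$phenotype)
  if (gen$data$modality == "binary")
    ph$phenotype <- gen$data$pheno_labels[gen$data$phenotype + 1L]
  data.table::fwrite(ph, file.path(dir, "phenotype.tsv"), sep = "\t")
  truth <- data.frame(
    block = rep(names(gen$truth$planted),
                vapply(gen$truth$planted, length, integer(1))),
    feature = unlist(gen$truth$planted, use.names = FALSE))
  data.table::fwrite(truth, file.path(dir, "ground_truth.tsv"), sep = "\t")
  invisible(dir)
}

#' A fixed, hand-checkable micro dataset
#'
#' Deterministic 12-subject dataset with two blocks of four features each.
#' The first two features of each block load on a shared factor; the
#' remaining features are fixed background noise. All values are hard-coded
#' literals, so closed-form oracles (ordinary least squares, outer products,
#' average linkage, power iteration, pruning enumeration) can be evaluated
#' by hand or frozen in tests.
#'
#' @return list with `data` (a quantitative `multiomics` dataset) and
#'   `truth` (latent factor values and planted feature names).
#' @export
worked_micro_example <- function() {
  z <- c(1.37, -0.56, 0.36, 0.63, 0.40, -0.11, 1.51, -0.09, 2.02, -0.06,
         1.30, 2.29)
  e1 <- matrix(c(
    -0.56, -0.11, -0.05, 0.25, -0.11, -1.06, -0.98, 0.53, -0.12, -0.71,
    -0.07, 0.49, 0.76, -0.17, -0.10, -0.71, 0.18, -0.26, 0.18, 0.28, 0.41,
    -0.24, 0.20, -0.69, -0.31, -0.34, -0.97, 0.01, 0.08, -0.14, 0.30,
    -0.29, -0.55, 0.17, -0.32, 0.58, -0.17, 0.26, 0.13, -0.31, 0.63, 0.26,
    0.04, 0.11, 0.27, 0.04, -1.20, 0.11), 12, 4)
  e2 <- matrix(c(
    -0.15, 0.07, 0.23, 0.56, -0.29, 0.52, 0.13, 0.42, 0.37, 0.29, -0.42,
    -0.04, 0.25, -0.38, -0.22, 0.23, 0.31, 0.19, -0.35, -0.44, 0.61, 0.10,
    0.04, -0.05, -0.48, 0.24, -0.09, -0.07, 0.37, 0.33, 0.56, -0.19, 0.26,
    0.56, -0.44, -0.34, -0.45, -0.58, 0.03, 0.26, 0.48, 0.42, -0.40, 0.74,
    -0.27, 0.04, -0.17, -0.05), 12, 4)
  ey <- c(0.06, 0.04, -0.01, 0.03, -0.15, -0.15, -0.50, -0.11, -0.15, 0.81,
          -0.41, 0.04)
  xa <- cbind(z + e1[, 1], z + e1[, 2], e1[, 3], e1[, 4])
  xb <- cbind(z + e2[, 1], z + e2[, 2], e2[, 3], e2[, 4])
  subjects <- sprintf("S%02d", 1:12)
  dimnames(xa) <- list(subjects, paste0("A_f", 1:4))
  dimnames(xb) <- list(subjects, paste0("B_f", 1:4))
  y <- z + ey
  names(y) <- subjects
  data <- multiomics_dataset(list(A = xa, B = xb), y,
                             modality = "quantitative")
  list(data = data,
       truth = list(factor = z,
                    planted = list(A = c("A_f1", "A_f2"),
                                   B = c("B_f1", "B_f2"))))
}
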