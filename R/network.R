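# Consensus network construction: feature subsampling, similarity-matrix
# accumulation from canonical weight snapshots, hierarchical module cutting.

#' Draw a feature subsample per block
#'
#' Uniform draws without replacement of `max(1, floor(fraction * p_t))`
#' column indices per block, deterministic given the seed.
#'
#' @param data a `multiomics` dataset.
#' @param fractions per-block fractions in (0, 1] (recycled if scalar).
#' @param iteration_seed integer seed.
#' @return named list of sorted integer index vectors.
#' @export
subsample_features <- function(data, fractions, iteration_seed) {
  labs <- names(data$blocks)
  if (length(fractions) == 1L) fractions <- rep(fractions, length(labs))
  if (any(fractions <= 0 | fractions > 1)) stop2("fractions must lie in (0, 1]")
  p <- block_sizes(data)
  sizes <- pmax(1L, as.integer(floor(fractions * p)))
  if (any(sizes == 0L)) stop2("subsample size 0")
  out <- with_seed(iteration_seed, {
    lapply(seq_along(labs), function(t) {
      if (sizes[t] == p[t]) seq_len(p[t]) else sort(sample.int(p[t], sizes[t]))
    })
  })
  stats::setNames(out, labs)
}

#' Aggregate weight snapshots into a consensus similarity matrix
#'
#' Averages the elementwise absolute outer product `|w w'|` of concatenated
#' canonical weight vectors over subsampling snapshots, rescales by the
#' maximum entry (if positive) so entries lie in `[0, 1]`, and zeroes the
#' diagonal.
#'
#' @param weight_snapshots list of numeric vectors, each the full-length
#'   concatenated weight vector (zeros at unsampled features), all the same
#'   length with identical names.
#' @return an object of class `similarity_matrix`: the symmetric matrix with
#'   attributes `n_subsamples` and (when available) `index`.
#' @export
accumulate_similarity <- function(weight_snapshots) {
  if (length(weight_snapshots) == 0L) stop2("no weight snapshots supplied")
  p <- length(weight_snapshots[[1L]])
  A <- matrix(0, p, p)
  for (w in weight_snapshots) {
    if (length(w) != p) stop2("snapshot lengths differ")
    aw <- abs(as.numeric(w))
    A <- A + outer(aw, aw)              # |w w'| = |w| |w|'
  }
  A <- A / length(weight_snapshots)
  diag(A) <- 0
  mx <- max(A)
  if (mx > 0) A <- A / mx
  nms <- names(weight_snapshots[[1L]])
  if (!is.null(nms)) dimnames(A) <- list(nms, nms)
  structure(A, n_subsamples = length(weight_snapshots),
            class = c("similarity_matrix", "matrix", "array"))
}

#' Build the consensus similarity matrix by feature subsampling
#'
#' Repeats `n_subsamples` times: draw a feature subsample, fit the canonical
#' weights on the subsampled columns ([solve_smcca()] for quantitative
#' phenotypes, [run_hybrid()] for binary), scatter the fitted weights into a
#' full-length vector (zeros elsewhere), and accumulate the absolute outer
#' products. Iteration seeds are derived deterministically from `seed`.
#' Individual iteration failures are logged and skipped; more than 50%
#' failures aborts.
#'
#' @param data a `multiomics` dataset.
#' @param penalties per-block penalties for the fit.
#' @param scaling optional [scaling_scheme()].
#' @param fractions per-block subsample fractions.
#' @param n_subsamples number of subsampling iterations.
#' @param seed master seed.
#' @param mode `"quantitative"` or `"binary"`.
#' @param binary_params list with `splsda_penalty`, `gamma1`, `gamma2`, `R`
#'   (binary mode only).
#' @return a `similarity_matrix` over all concatenated features
#'   (block-prefixed names).
#' @export
run_subsampling <- function(data, penalties, scaling = NULL, fractions = 1,
                            n_subsamples = 100L, seed = 1L,
                            mode = c("quantitative", "binary"),
                            binary_params = NULL) {
  mode <- match.arg(mode)
  if (n_subsamples < 1L) stop2("n_subsamples must be >= 1")
  labs <- names(data$blocks)
  cc <- concat_blocks(data)
  p_total <- ncol(cc$x)
  offsets <- c(0L, cumsum(block_sizes(data)))
  seeds <- derive_seeds(seed, n_subsamples)
  snapshots <- vector("list", n_subsamples)
  failures <- 0L
  for (it in seq_len(n_subsamples)) {
    snap <- tryCatch({
      idx <- subsample_features(data, fractions, seeds[it])
      sub <- subset_features(data, idx)
      w <- if (mode == "quantitative") {
        fit <- suppressWarnings(solve_smcca(sub, penalties, scaling = scaling))
        fit$weights
      } else {
        bp <- binary_params %||% list()
        fit <- suppressMessages(suppressWarnings(run_hybrid(
          sub, smcca_penalties = penalties,
          splsda_penalty = bp$splsda_penalty %||% 0.9,
          gamma1 = bp$gamma1 %||% 1, gamma2 = bp$gamma2 %||% 1,
          R = bp$R %||% 3L, scaling = scaling)))
        fit$weights
      }
      full <- numeric(p_total)
      for (t in seq_along(labs))
        full[offsets[t] + idx[[t]]] <- w[[t]]
      names(full) <- colnames(cc$x)
      full
    }, error = function(e) {
      msg("subsample iteration %d failed: %s", it, conditionMessage(e))
      NULL
    })
    if (is.null(snap)) failures <- failures + 1L else snapshots[[it]] <- snap
  }
  if (failures > n_subsamples / 2)
    stop2("%d of %d subsampling iterations failed", failures, n_subsamples)
  sim <- accumulate_similarity(Filter(Negate(is.null), snapshots))
  attr(sim, "index") <- cc$index
  sim
}

#' Cut the similarity tree into candidate modules
#'
#' Average-linkage hierarchical clustering on the dissimilarity
#' `1 - similarity`, cut at `cut_height`; clusters smaller than `min_size`
#' are discarded (smaller clusters could never survive pruning).
#'
#' @param similarity a `similarity_matrix`.
#' @param cut_height tree cut height in (0, 1].
#' @param min_size minimum module size (>= 2).
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @return an object of class `module_partition`: list with `modules`
#'   (list of sorted integer feature indices), `features` (their names),
#'   `cut_height`, `linkage`.
#' @export
cluster_modules <- function(similarity, cut_height, min_size = 10L,
                            linkage = "average") {
  if (cut_height <= 0 || cut_height > 1) stop2("cut_height must lie in (0, 1]")
  if (min_size < 2L) stop2("min_size must be >= 2")
  D <- 1 - unclass(similarity)
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  groups <- stats::cutree(hc, h = cut_height)
  mods <- split(seq_along(groups), groups)
  keep <- vapply(mods, length, integer(1)) >= min_size
  if (sum(!keep) > 0)
    msg("discarded %d cluster(s) below min_size %d", sum(!keep), min_size)
  mods <- unname(mods[keep])
  if (length(mods) == 0L)
    warn2("no module of size >= %d at cut height %g", min_size, cut_height)
  nms <- colnames(similarity)
  structure(
    list(modules = lapply(mods, sort),
         features = lapply(mods, function(m) nms[sort(m)]),
         cut_height = cut_height, linkage = linkage),
    class = "module_partition"
  )
}

#' Write a similarity matrix as dense and sparse TSV
#'
#' @param similarity a `similarity_matrix`.
#' @param path dense TSV output path; the sparse triplet file (feature_a,
#'   feature_b, similarity; upper triangle, nonzero entries) goes to
#'   `paste0(path, ".triplets")` unless `sparse_path` is given.
#' @param sparse_path optional triplet file path (`NULL` to skip).
#' @return `path`, invisibly.
#' @export
write_similarity <- function(similarity, path,
                             sparse_path = paste0(path, ".triplets")) {
  m <- unclass(similarity)
  attr(m, "n_subsamples") <- NULL
  attr(m, "index") <- NULL
  write_matrix_tsv(m, path, id_name = "feature")
  if (!is.null(sparse_path)) {
    ut <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
    trip <- data.frame(feature_a = rownames(m)[ut[, 1L]],
                       feature_b = colnames(m)[ut[, 2L]],
                       similarity = m[ut])
    data.table::fwrite(trip, sparse_path, sep = "\t")
  }
  invisible(path)
}
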