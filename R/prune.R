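# Module summarization and pruning: PageRank feature ranking, PCA / NetSHy
# summarization scores, and the m* / x / m_opt pruning search.

#' Weighted PageRank scores for a module graph
#'
#' Stationary-distribution node importance on the weighted undirected graph
#' defined by a nonnegative adjacency matrix (damping 0.85). Scores sum to
#' 1; an all-zero adjacency yields uniform scores with a warning.
#'
#' @param adjacency symmetric nonnegative matrix (diagonal ignored).
#' @param damping damping factor (default 0.85).
#' @return numeric vector of PageRank scores (named like the adjacency).
#' @export
pagerank_scores <- function(adjacency, damping = 0.85) {
  A <- as.matrix(unclass(adjacency))
  if (nrow(A) < 2L) stop2("PageRank needs at least 2 nodes")
  diag(A) <- 0
  if (any(A < 0)) stop2("adjacency must be nonnegative")
  if (max(A) == 0) {
    warn2("all-zero adjacency; uniform PageRank scores returned")
    return(stats::setNames(rep(1 / nrow(A), nrow(A)), rownames(A)))
  }
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  pr <- igraph::page_rank(g, damping = damping,
                          weights = igraph::E(g)$weight)$vector
  stats::setNames(as.numeric(pr), rownames(A))
}

# Shared post-processing: keep at most 3 informative components, apply the
# deterministic sign convention (largest-|loading| coordinate positive).
finalize_components <- function(scores, loadings, sdev, method) {
  keep <- which(sdev > 1e-10)
  k <- min(3L, length(keep))
  if (k < 1L) stop2("summarization input has no variance")
  scores <- scores[, seq_len(k), drop = FALSE]
  loadings <- loadings[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = loadings, method = method),
            class = "summarization")
}

#' PCA summarization of a module submatrix
#'
#' First three principal components (fewer when rank-limited) of the
#' column-standardized subjects x features submatrix, with deterministic
#' loading signs.
#'
#' @param submatrix numeric matrix, subjects x module features.
#' @return an object of class `summarization`: `scores` (subjects x k,
#'   column-centered), `loadings` (features x k, orthonormal), `method`.
#' @export
pca_summarize <- function(submatrix) {
  x <- as.matrix(submatrix)
  if (ncol(x) < 2L || nrow(x) < 3L) stop2("PCA needs >= 2 features and >= 3 subjects")
  xs <- center_scale(x)
  pr <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  finalize_components(pr$x, pr$rotation, pr$sdev, "pca")
}

# Topology operator used by NetSHy: symmetric normalized graph Laplacian of
# the max-normalized adjacency; rows/columns of isolated nodes are zero so
# an edgeless module contributes no propagated signal.
netshy_laplacian <- function(adjacency) {
  A <- as.matrix(unclass(adjacency))
  diag(A) <- 0
  if (max(A) > 0) A <- A / max(A)
  deg <- rowSums(A)
  dhalf <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  L <- diag(as.numeric(deg > 0)) - (dhalf %o% dhalf) * A
  dimnames(L) <- dimnames(A)
  L
}

#' Topology-aware (NetSHy) summarization
#'
#' PCA applied to the column concatenation of the standardized submatrix `X`
#' and its topology-propagated copy `X L`, where `L` is the symmetric
#' normalized graph Laplacian of the module adjacency. The propagation term
#' lets densely connected features shape the leading components. The
#' operator is a pluggable strategy; alternatives can replace
#' the Laplacian without touching the pruner.
#'
#' @param submatrix numeric matrix, subjects x module features.
#' @param adjacency induced similarity submatrix for the same features (in
#'   the same order).
#' @return a `summarization` whose `loadings` rows cover both the direct
#'   (rows 1..p) and the propagated (rows p+1..2p) coordinates.
#' @export
netshy_summarize <- function(submatrix, adjacency) {
  x <- as.matrix(submatrix)
  A <- as.matrix(unclass(adjacency))
  if (ncol(x) != nrow(A) || nrow(A) != ncol(A))
    stop2("adjacency dimensions do not match the submatrix features")
  xs <- center_scale(x)
  L <- netshy_laplacian(A)
  M <- cbind(xs, xs %*% L)
  colnames(M) <- c(colnames(xs), paste0(colnames(xs), ".prop"))
  pr <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  finalize_components(pr$x, pr$rotation, pr$sdev, "netshy")
}

#' Best phenotype correlation among summarization components
#'
#' Pearson correlation of each component score with the phenotype (0/1
#' coding for binary, i.e. point-biserial) and selection of the component
#' maximizing the absolute correlation.
#'
#' @param summary a `summarization`.
#' @param phenotype numeric phenotype vector aligned with the score rows (a
#'   `multiomics` dataset is also accepted).
#' @return list with `rho` (signed correlation of the winning component),
#'   `which_pc` (its index), `rho_all` (all components).
#' @export
correlation_to_phenotype <- function(summary, phenotype) {
  y <- if (inherits(phenotype, "multiomics")) phenotype$phenotype else as.numeric(phenotype)
  if (length(y) != nrow(summary$scores))
    stop2("phenotype length does not match score rows")
  rho <- apply(summary$scores, 2L, function(s) {
    if (stats::sd(s) == 0) 0 else stats::cor(s, y)
  })
  k <- which.max(abs(rho))
  list(rho = unname(rho[k]), which_pc = unname(k), rho_all = unname(rho))
}

summarize_module <- function(x, adjacency, method) {
  if (method == "pca") pca_summarize(x) else netshy_summarize(x, adjacency)
}

#' Prune a module by PageRank-ordered summarization search
#'
#' Features are ranked by PageRank on the induced similarity graph. For each
#' size `i` in `[m1, m2]` the top-`i` features are summarized and the best
#' absolute component correlation with the phenotype, `rho(i, pheno)`, is
#' recorded. Then: `m*` is the size maximizing `|rho(i, pheno)|` (ties:
#' smallest); `x` is the largest size in `[m*, m2]` whose summarization
#' score still correlates above 0.8 (in absolute value) with the size-`m*`
#' score; `m_opt` is the largest size in `[m*, x]` retaining at least 90% of
#' `|rho(m*, pheno)|`.
#'
#' @param features feature names or indices (into `similarity`) of the
#'   module.
#' @param similarity the full `similarity_matrix`.
#' @param data the `multiomics` dataset (standardized blocks).
#' @param m1,m2 minimum and maximum candidate sizes (`m2` is clamped to the
#'   module size).
#' @param method `"netshy"` (default) or `"pca"`.
#' @return an object of class `pruned_module`: list with `features`
#'   (retained, in PageRank order), `adjacency` (induced), `summarization`,
#'   `correlation_to_phenotype`, `which_pc`, `trace` (fields `m1`, `m2`,
#'   `ranked_features`, `rho_pheno`, `rho_base`, `m_star`, `x`, `m_opt`).
#' @export
prune_network <- function(features, similarity, data, m1 = 10L, m2 = 100L,
                          method = c("netshy", "pca")) {
  method <- match.arg(method)
  S <- unclass(similarity)
  feats <- if (is.character(features)) match(features, colnames(S)) else as.integer(features)
  if (anyNA(feats)) stop2("unknown feature(s) in module")
  msize <- length(feats)
  if (m1 < 2L) stop2("m1 must be >= 2")
  if (m1 > msize) stop2("m1 = %d exceeds the module size %d", m1, msize)
  m2 <- min(m2, msize)
  if (m2 < m1) stop2("m2 < m1 after clamping")

  adj <- S[feats, feats, drop = FALSE]
  pr <- suppressWarnings(pagerank_scores(adj))
  ranked <- feats[order(-pr, seq_along(pr))]
  cc <- concat_blocks(data)
  xmod <- cc$x[, ranked, drop = FALSE]

  sizes <- m1:m2
  rho_pheno <- numeric(length(sizes))
  best_scores <- vector("list", length(sizes))
  for (s in seq_along(sizes)) {
    i <- sizes[s]
    summ <- summarize_module(xmod[, seq_len(i), drop = FALSE],
                             S[ranked[seq_len(i)], ranked[seq_len(i)], drop = FALSE],
                             method)
    ct <- correlation_to_phenotype(summ, data$phenotype)
    rho_pheno[s] <- ct$rho
    best_scores[[s]] <- summ$scores[, ct$which_pc]
  }
  names(rho_pheno) <- sizes

  m_star <- sizes[which.max(abs(rho_pheno))]
  base <- best_scores[[match(m_star, sizes)]]
  upper <- sizes[sizes >= m_star]
  rho_base <- vapply(upper, function(i) {
    s <- best_scores[[match(i, sizes)]]
    if (stats::sd(s) == 0 || stats::sd(base) == 0) 0 else abs(stats::cor(base, s))
  }, numeric(1))
  names(rho_base) <- upper
  x_size <- max(upper[rho_base > 0.8])
  cand <- sizes[sizes >= m_star & sizes <= x_size]
  ok <- abs(rho_pheno[match(cand, sizes)]) >= 0.9 * abs(rho_pheno[match(m_star, sizes)])
  m_opt <- max(cand[ok])

  kept <- ranked[seq_len(m_opt)]
  final_adj <- S[kept, kept, drop = FALSE]
  final_summ <- summarize_module(cc$x[, kept, drop = FALSE], final_adj, method)
  final_ct <- correlation_to_phenotype(final_summ, data$phenotype)
  trace <- list(m1 = m1, m2 = m2, ranked_features = colnames(S)[ranked],
                pagerank = sort(pr, decreasing = TRUE),
                rho_pheno = rho_pheno, rho_base = rho_base,
                m_star = m_star, x = x_size, m_opt = m_opt)
  structure(
    list(features = colnames(S)[kept], feature_idx = kept,
         adjacency = final_adj, summarization = final_summ,
         correlation_to_phenotype = final_ct$rho, which_pc = final_ct$which_pc,
         method = method, trace = trace),
    class = "pruned_module"
  )
}

#' Summary table across pruned modules
#'
#' One row per module: index, pruned size, best component correlation with
#' the phenotype, and per-block feature counts (which sum to the size).
#'
#' @param pruned list of `pruned_module` objects.
#' @param data the `multiomics` dataset.
#' @return data.frame with columns `module`, `size`,
#'   `pc_correlation_to_phenotype`, and `n_<block>` per block.
#' @export
module_summary_table <- function(pruned, data) {
  labs <- names(data$blocks)
  rows <- lapply(seq_along(pruned), function(k) {
    pm <- pruned[[k]]
    blocks_of <- sub(":.*$", "", pm$features)
    counts <- vapply(labs, function(l) sum(blocks_of == l), integer(1))
    out <- data.frame(module = k, size = length(pm$features),
                      pc_correlation_to_phenotype = pm$correlation_to_phenotype)
    for (l in labs) out[[paste0("n_", l)]] <- counts[[l]]
    out
  })
  do.call(rbind, rows)
}
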