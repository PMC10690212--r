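# Automated end-to-end driver: mode detection, heuristics, orchestration,
# and text-based result persistence.

#' Detect the analysis mode
#'
#' @param data a `multiomics` dataset.
#' @return one of `"single-quantitative"`, `"single-binary"`,
#'   `"multi-quantitative"`, `"multi-binary"`.
#' @export
detect_mode <- function(data) {
  paste0(if (length(data$blocks) == 1L) "single" else "multi",
         "-", data$modality)
}

#' Automated subsample fraction heuristic
#'
#' Blocks with fewer than 300 features use fraction 0.9; wider blocks use
#' 0.7 (strict inequality at the boundary).
#'
#' @param p number of features in the block.
#' @return 0.9 or 0.7.
#' @export
auto_subsample_fraction <- function(p) {
  if (p < 1) stop2("p must be >= 1")
  if (p < 300) 0.9 else 0.7
}

#' Automated gamma weights for the binary hybrid
#'
#' `gamma1` (omics-omics importance) is the mean absolute preliminary
#' pairwise canonical correlation; `gamma2` (omics-phenotype importance) is
#' fixed at 1. When every correlation is 0 the hybrid weight reduces to the
#' discriminant part alone.
#'
#' @param pairwise_cc data.frame from [pairwise_preliminary_cc()] (or any
#'   data.frame with a `cc` column).
#' @return list with `gamma1`, `gamma2`.
#' @export
auto_gamma <- function(pairwise_cc) {
  if (is.null(pairwise_cc$cc) || length(pairwise_cc$cc) == 0L)
    stop2("pairwise correlation table is empty")
  list(gamma1 = mean(abs(pairwise_cc$cc)), gamma2 = 1)
}

#' Default penalty grids per mode
#'
#' Quantitative modes search per-block penalties 0.1 to 0.5 (step 0.1);
#' binary modes search 0.5 to 0.9 (step 0.1) per block and for the
#' classifier penalty.
#'
#' @param mode a [detect_mode()] tag.
#' @param block_labels character vector of block labels.
#' @return a [build_penalty_grid()] result.
#' @export
default_grids <- function(mode, block_labels) {
  quant <- grepl("quantitative", mode)
  cand <- if (quant) seq(0.1, 0.5, by = 0.1) else seq(0.5, 0.9, by = 0.1)
  per_block <- stats::setNames(rep(list(cand), length(block_labels)), block_labels)
  build_penalty_grid(per_block,
                     classifier = if (quant) NULL else cand)
}

#' Run the automated end-to-end pipeline
#'
#' Orchestrates: optional per-block standardization, mode detection,
#' scaling-factor / gamma heuristics, penalty cross-validation, subsampled
#' similarity construction, hierarchical module detection, per-module
#' pruning, and persistence of every artifact (TSV/GraphML + JSON manifest)
#' under `out_dir`. All randomness flows from `seed`.
#'
#' @param data a `multiomics` dataset (raw or standardized blocks).
#' @param out_dir output directory (`NULL` to skip persistence).
#' @param K cross-validation folds.
#' @param n_subsamples subsampling iterations.
#' @param cut_height hierarchical tree cut height in (0, 1].
#' @param summarization `"netshy"` or `"pca"`.
#' @param between_shrinkage shrinkage divisor for automated between-omics
#'   scaling factors (multi-omics modes).
#' @param m1,m2 pruning size bounds; `m1` doubles as the minimum module
#'   size.
#' @param eval_method binary CV metric (`"auc"` default).
#' @param seed master seed.
#' @param edge_threshold absolute Pearson threshold for exported edges.
#' @param penalty_grid optional grid overriding [default_grids()].
#' @param subsample_fractions optional per-block fractions overriding
#'   [auto_subsample_fraction()].
#' @param preliminary_penalty stringent penalty for
#'   [pairwise_preliminary_cc()].
#' @param standardize if `TRUE` (default), blocks are centered/scaled first.
#' @return an object of class `run_result`: list with `mode`, `scaling`,
#'   `gamma`, `cv`, `similarity`, `partition`, `pruned`, `summary_table`,
#'   `config`.
#' @export
run_pipeline <- function(data, out_dir = NULL, K = 5L, n_subsamples = 100L,
                         cut_height = 0.995, summarization = c("netshy", "pca"),
                         between_shrinkage = 5, m1 = 10L, m2 = 100L,
                         eval_method = "auc", seed = 1L, edge_threshold = 0,
                         penalty_grid = NULL, subsample_fractions = NULL,
                         preliminary_penalty = 0.1, standardize = TRUE) {
  summarization <- match.arg(summarization)
  if (cut_height <= 0 || cut_height > 1) stop2("cut_height must lie in (0, 1]")
  if (K < 2L) stop2("K must be >= 2")
  labs <- names(data$blocks)
  if (standardize) data$blocks <- lapply(data$blocks, center_scale)
  mode <- detect_mode(data)
  msg("mode: %s", mode)
  multi <- length(labs) > 1L
  binary <- data$modality == "binary"

  scaling <- NULL
  gamma <- NULL
  if (multi) {
    pcc <- pairwise_preliminary_cc(data, penalty = preliminary_penalty)
    scaling <- auto_scaling_factors(pcc, between_shrinkage)
    if (binary) gamma <- auto_gamma(pcc)
  }

  grid <- penalty_grid %||% default_grids(mode, labs)
  if (binary) {
    cv <- cv_binary(data, grid, K = K, seed = seed, eval_method = eval_method,
                    gamma1 = if (multi) gamma$gamma1 else 0,
                    gamma2 = if (multi) gamma$gamma2 else 1,
                    scaling = scaling)
    best_pen <- cv$best_penalties
    binary_params <- list(splsda_penalty = cv$best_classifier,
                          gamma1 = if (multi) gamma$gamma1 else 0,
                          gamma2 = if (multi) gamma$gamma2 else 1, R = 3L)
  } else {
    cv <- cv_quantitative(data, grid, scaling = scaling, K = K, seed = seed)
    best_pen <- cv$best_penalties
    binary_params <- NULL
  }
  msg("selected penalties: %s",
      paste(sprintf("%s=%.3g", names(best_pen), best_pen), collapse = ", "))

  fractions <- subsample_fractions %||%
    vapply(block_sizes(data), auto_subsample_fraction, numeric(1))
  sim <- run_subsampling(data, best_pen, scaling = scaling,
                         fractions = fractions, n_subsamples = n_subsamples,
                         seed = seed,
                         mode = if (binary) "binary" else "quantitative",
                         binary_params = binary_params)
  partition <- cluster_modules(sim, cut_height, min_size = m1)
  pruned <- lapply(partition$modules, function(mfeats)
    suppressWarnings(prune_network(mfeats, sim, data, m1 = m1, m2 = m2,
                                   method = summarization)))
  summary_table <- if (length(pruned) > 0) module_summary_table(pruned, data)
                   else data.frame()

  config <- list(K = K, n_subsamples = n_subsamples, cut_height = cut_height,
                 summarization = summarization,
                 between_shrinkage = between_shrinkage, m1 = m1, m2 = m2,
                 eval_method = eval_method, seed = seed,
                 edge_threshold = edge_threshold,
                 subsample_fractions = as.numeric(fractions),
                 preliminary_penalty = preliminary_penalty,
                 standardize = standardize, mode = mode)
  result <- structure(
    list(mode = mode, scaling = scaling, gamma = gamma, cv = cv,
         similarity = sim, partition = partition, pruned = pruned,
         summary_table = summary_table, config = config, data = data),
    class = "run_result"
  )
  if (!is.null(out_dir)) persist_run(result, out_dir)
  result
}

round3 <- function(x) round(x, 3)

persist_run <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(result$summary_table,
                     file.path(out_dir, "summary_table.tsv"), sep = "\t")
  write_cv_table(result$cv, file.path(out_dir, "cv_table.tsv"))
  write_similarity(result$similarity, file.path(out_dir, "similarity.tsv"))
  module_dirs <- character(0)
  for (k in seq_along(result$pruned)) {
    mdir <- file.path(out_dir, sprintf("module_%d", k))
    dir.create(mdir, showWarnings = FALSE)
    write_pruned_module(result$pruned[[k]], result$data, mdir,
                        edge_threshold = result$config$edge_threshold)
    module_dirs <- c(module_dirs, basename(mdir))
  }
  manifest <- list(
    package = "moccanet",
    version = as.character(utils::packageVersion("moccanet")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = result$config,
    scaling_between = if (!is.null(result$scaling)) round3(result$scaling$between),
    scaling_pheno = if (!is.null(result$scaling)) round3(result$scaling$pheno),
    gamma = result$gamma,
    selected_penalties = as.list(result$cv$best_penalties),
    selected_classifier_penalty = result$cv$best_classifier,
    n_modules = length(result$pruned),
    files = c("summary_table.tsv", "cv_table.tsv", "similarity.tsv",
              module_dirs)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  msg("results written to %s", out_dir)
  invisible(out_dir)
}

write_pruned_module <- function(pruned, data, dir, edge_threshold = 0) {
  cc <- concat_blocks(data)
  feats <- pruned$features
  tr <- pruned$trace
  load_x <- pruned$summarization$loadings[seq_along(feats), , drop = FALSE]
  ft <- data.frame(
    feature = feats,
    block = sub(":.*$", "", feats),
    pagerank = as.numeric(tr$pagerank[feats]),
    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(load_x)))
    ft[[paste0("loading_PC", j)]] <- load_x[, j]
  ft$phenotype_correlation <- vapply(feats, function(f)
    stats::cor(cc$x[, f], data$phenotype), numeric(1))
  data.table::fwrite(ft, file.path(dir, "features.tsv"), sep = "\t")
  write_matrix_tsv(pruned$adjacency, file.path(dir, "adjacency.tsv"),
                   id_name = "feature")
  sc <- pruned$summarization$scores
  rownames(sc) <- data$subjects
  write_matrix_tsv(sc, file.path(dir, "scores.tsv"), id_name = "subject")
  trace_df <- data.frame(size = as.integer(names(tr$rho_pheno)),
                         rho_pheno = as.numeric(tr$rho_pheno))
  trace_df$rho_base <- tr$rho_base[as.character(trace_df$size)]
  trace_df$m_star <- tr$m_star
  trace_df$x <- tr$x
  trace_df$m_opt <- tr$m_opt
  data.table::fwrite(trace_df, file.path(dir, "trace.tsv"), sep = "\t")
  export_module_graph(pruned, data, edge_threshold = edge_threshold, dir = dir)
  invisible(dir)
}

#' Export a pruned module as edge list and GraphML
#'
#' Writes `edges.tsv` (feature_a, feature_b, similarity, pearson_r) keeping
#' edges with positive similarity and `|pearson_r| >= edge_threshold`, and
#' `graph.graphml` with node attributes (block, component loadings,
#' feature-phenotype correlation). Nodes are always listed even when every
#' edge is filtered out.
#'
#' @param pruned a `pruned_module`.
#' @param data the `multiomics` dataset.
#' @param edge_threshold absolute Pearson correlation cutoff in [0, 1).
#' @param dir output directory.
#' @return data.frame of surviving edges, invisibly.
#' @export
export_module_graph <- function(pruned, data, edge_threshold = 0, dir = ".") {
  if (edge_threshold < 0 || edge_threshold >= 1)
    stop2("edge_threshold must lie in [0, 1)")
  cc <- concat_blocks(data)
  feats <- pruned$features
  x <- cc$x[, feats, drop = FALSE]
  r <- stats::cor(x)
  A <- pruned$adjacency
  ut <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  edges <- data.frame(
    feature_a = feats[ut[, 1L]], feature_b = feats[ut[, 2L]],
    similarity = A[ut], pearson_r = r[ut],
    stringsAsFactors = FALSE)
  edges <- edges[abs(edges$pearson_r) >= edge_threshold, , drop = FALSE]
  if (nrow(edges) == 0L)
    msg("edge filter at |r| >= %g removed every edge; nodes still exported",
        edge_threshold)
  data.table::fwrite(edges, file.path(dir, "edges.tsv"), sep = "\t")

  g <- igraph::make_empty_graph(n = length(feats), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = feats)
  g <- igraph::set_vertex_attr(g, "block", value = sub(":.*$", "", feats))
  load_x <- pruned$summarization$loadings[seq_along(feats), , drop = FALSE]
  for (j in seq_len(ncol(load_x)))
    g <- igraph::set_vertex_attr(g, paste0("loading_PC", j), value = load_x[, j])
  g <- igraph::set_vertex_attr(
    g, "phenotype_correlation",
    value = vapply(feats, function(f) stats::cor(cc$x[, f], data$phenotype),
                   numeric(1)))
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(match(edges$feature_a, feats),
                                    match(edges$feature_b, feats)))
    g <- igraph::set_edge_attr(g, "similarity", value = edges$similarity)
    g <- igraph::set_edge_attr(g, "pearson_r", value = edges$pearson_r)
  }
  igraph::write_graph(g, file.path(dir, "graph.graphml"), format = "graphml")
  invisible(edges)
}
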