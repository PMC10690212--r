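# Model selection: k-fold cross-validation over penalty grids with the
# scaled prediction error loss (quantitative) or classification metrics
# (binary), plus the three scaling-factor selection schemes.

#' Scaled prediction error
#'
#' The cross-validation loss `|trainCC - testCC| / |testCC|`, which penalizes
#' both the train/test discrepancy and small test canonical correlations.
#' `testCC = 0` yields `+Inf` so degenerate combinations are never selected.
#'
#' @param trainCC,testCC training and testing canonical correlations.
#' @return nonnegative numeric (possibly `Inf`).
#' @export
scaled_prediction_error <- function(trainCC, testCC) {
  ifelse(testCC == 0, Inf, abs(trainCC - testCC) / abs(testCC))
}

#' Build a penalty grid
#'
#' Enumerates the Cartesian product of per-block candidate penalties (and,
#' in binary mode, classifier penalty candidates) in deterministic row-major
#' order (first block varies slowest).
#'
#' @param per_block named list of candidate vectors (values in (0, 1]), one
#'   per block.
#' @param classifier optional candidate vector for the discriminant penalty.
#' @return data.frame of class `penalty_grid`, one row per combination, with
#'   one column per block (plus `classifier` if supplied).
#' @export
build_penalty_grid <- function(per_block, classifier = NULL) {
  if (length(per_block) == 0L || any(vapply(per_block, length, integer(1)) == 0L))
    stop2("every block needs a non-empty candidate list")
  cands <- per_block
  if (!is.null(classifier)) {
    if (length(classifier) == 0L) stop2("classifier candidate list is empty")
    cands <- c(cands, list(classifier = classifier))
  }
  for (v in cands)
    if (any(v <= 0 | v > 1)) stop2("penalty candidates must lie in (0, 1]")
  if (is.null(names(per_block)))
    names(cands)[seq_along(per_block)] <- paste0("block", seq_along(per_block))
  grid <- rev(expand.grid(rev(cands), KEEP.OUT.ATTRS = FALSE))
  rownames(grid) <- NULL
  class(grid) <- c("penalty_grid", "data.frame")
  grid
}

#' Assign subjects to cross-validation folds
#'
#' Deterministic k-fold assignment: every subject lands in exactly one test
#' fold and fold sizes differ by at most one. With `stratify_labels`, fold
#' assignment cycles within each class so per-class counts are balanced, and
#' an error is raised if any training fold would miss a class.
#'
#' @param n number of subjects.
#' @param K number of folds, `2 <= K <= n`.
#' @param seed integer seed.
#' @param stratify_labels optional binary label vector of length `n`.
#' @return integer vector of fold indices in `1:K`.
#' @export
kfold_split <- function(n, K, seed, stratify_labels = NULL) {
  if (K < 2L || K > n) stop2("K must satisfy 2 <= K <= n (n = %d, K = %d)", n, K)
  folds <- integer(n)
  if (is.null(stratify_labels)) {
    ord <- with_seed(seed, sample.int(n))
    folds[ord] <- rep(seq_len(K), length.out = n)
  } else {
    if (length(stratify_labels) != n) stop2("stratify_labels length mismatch")
    cycle <- 0L
    for (cls in sort(unique(as.character(stratify_labels)))) {
      idx <- which(as.character(stratify_labels) == cls)
      ord <- with_seed(seed + cycle, sample(idx))
      folds[ord] <- ((cycle + seq_along(ord) - 1L) %% K) + 1L
      cycle <- cycle + length(ord)
    }
    for (cls in unique(as.character(stratify_labels))) {
      in_cls <- as.character(stratify_labels) == cls
      fold_counts <- tabulate(folds[in_cls], nbins = K)
      if (any(fold_counts == sum(in_cls)))  # a test fold holds the whole class
        stop2("a class would be absent from some training fold; use a smaller K")
    }
  }
  folds
}

# Scaling-weighted sum of pairwise score correlations, with the active
# scaling factors normalized to sum to one. The canonical correlation
# summary used for both trainCC and testCC.
total_canonical_correlation <- function(data, weights, scaling) {
  cors <- suppressWarnings(score_correlations(data, weights))
  labs <- names(data$blocks)
  wts <- numeric(nrow(cors))
  for (k in seq_len(nrow(cors))) {
    i <- cors$block_i[k]
    j <- cors$block_j[k]
    wts[k] <- if (j == "phenotype") scaling$pheno[i] else scaling$between[i, j]
  }
  if (sum(wts) == 0) return(0)
  sum(wts / sum(wts) * cors$correlation)
}

#' Cross-validate penalties for a quantitative phenotype
#'
#' For every grid combination and fold, fits [solve_smcca()] on the training
#' subjects and evaluates the scaling-weighted total canonical correlation on
#' training and held-out subjects. Fold-averaged trainCC/testCC feed the
#' scaled prediction error once per combination; the minimizer wins (ties:
#' smallest penalties in lexicographic block order).
#'
#' @param data a `multiomics` dataset (quantitative phenotype).
#' @param grid a [build_penalty_grid()] result without classifier column.
#' @param scaling a [scaling_scheme()] or `NULL` for unweighted.
#' @param K number of folds.
#' @param seed integer seed for the fold split.
#' @return an object of class `cv_result`: list with `table` (one row per
#'   combination: penalties, `train_cc`, `test_cc`, `loss`), `best` (row
#'   index), `best_penalties`, `metric = "scaled_prediction_error"`.
#' @export
cv_quantitative <- function(data, grid, scaling = NULL, K = 5L, seed = 1L) {
  if (data$modality != "quantitative")
    stop2("cv_quantitative requires a quantitative phenotype")
  labs <- names(data$blocks)
  if (is.null(scaling)) scaling <- uniform_scaling(labs)
  pen_cols <- setdiff(names(grid), "classifier")
  if (length(pen_cols) != length(labs))
    stop2("grid has %d penalty columns but the dataset has %d blocks",
          length(pen_cols), length(labs))
  folds <- kfold_split(n_subjects(data), K, seed)
  train_cc <- test_cc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pens <- stats::setNames(as.numeric(grid[g, pen_cols]), labs)
    tr <- te <- numeric(K)
    for (k in seq_len(K)) {
      train <- subset_subjects(data, folds != k)
      test <- subset_subjects(data, folds == k)
      fit <- suppressWarnings(solve_smcca(train, pens, scaling = scaling))
      tr[k] <- total_canonical_correlation(train, fit, scaling)
      te[k] <- total_canonical_correlation(test, fit, scaling)
    }
    train_cc[g] <- mean(tr)
    test_cc[g] <- mean(te)
  }
  loss <- scaled_prediction_error(train_cc, test_cc)
  tab <- cbind(grid, train_cc = train_cc, test_cc = test_cc, loss = loss)
  class(tab) <- "data.frame"
  best <- pick_best(tab[pen_cols], loss, maximize = FALSE)
  structure(
    list(table = tab, best = best,
         best_penalties = stats::setNames(as.numeric(grid[best, pen_cols]), labs),
         metric = "scaled_prediction_error", K = K, seed = seed),
    class = "cv_result"
  )
}

# Deterministic winner: optimal value, then lexicographically smallest
# penalties across columns in order.
pick_best <- function(pen_df, value, maximize) {
  opt <- if (maximize) max(value[is.finite(value)]) else min(value)
  cand <- which(if (maximize) value >= opt - 1e-12 else value <= opt + 1e-12)
  if (length(cand) == 1L) return(cand)
  ord <- do.call(order, as.list(pen_df[cand, , drop = FALSE]))
  cand[ord[1L]]
}

#' Classification metrics for binary scores
#'
#' Accuracy, AUC, precision, recall and F1 for predicted probabilities
#' against binary labels. AUC is pairwise concordance with half credit for
#' ties; thresholded metrics predict the positive class when `score > 0.5`.
#' Precision (and hence F1) is 0 when no positive is predicted.
#'
#' @param labels binary vector (the lexicographically larger label is the
#'   positive class, matching the dataset's 0/1 coding).
#' @param scores numeric vector of predicted probabilities.
#' @return named numeric vector `accuracy`, `auc`, `precision`, `recall`,
#'   `f1`.
#' @export
classification_metrics <- function(labels, scores) {
  y <- code_labels(labels)
  if (length(y) != length(scores)) stop2("labels/scores length mismatch")
  pos <- y == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  r <- rank(scores)                     # midranks give ties 0.5 credit
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- as.numeric(scores > 0.5)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  accuracy <- mean(pred == y)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(accuracy = accuracy, auc = auc, precision = precision,
    recall = recall, f1 = f1)
}

cv_eval_methods <- c("accuracy", "auc", "precision", "recall", "f1")

#' Cross-validate penalties for a binary phenotype
#'
#' For every grid combination (per-block CCA penalties plus a classifier
#' penalty) and stratified fold, runs the full hybrid algorithm on the
#' training subjects, scores held-out subjects through the stored logistic
#' aggregation, and averages the chosen metric across folds. The maximizer
#' wins (ties: smallest penalties lexicographically).
#'
#' @param data a `multiomics` dataset (binary phenotype).
#' @param grid a [build_penalty_grid()] result with a `classifier` column.
#' @param K number of folds.
#' @param seed integer seed.
#' @param eval_method one of `"accuracy"`, `"auc"`, `"precision"`,
#'   `"recall"`, `"f1"`.
#' @param gamma1,gamma2,R,scaling passed to [run_hybrid()].
#' @return a `cv_result` with `table` (penalties + `metric` column),
#'   `best`, `best_penalties` (block penalties), `best_classifier`.
#' @export
cv_binary <- function(data, grid, K = 5L, seed = 1L, eval_method = "auc",
                      gamma1 = 1, gamma2 = 1, R = 3L, scaling = NULL) {
  if (data$modality != "binary") stop2("cv_binary requires a binary phenotype")
  if (!eval_method %in% cv_eval_methods)
    stop2("unknown eval_method '%s'; valid: %s", eval_method,
          paste(cv_eval_methods, collapse = ", "))
  labs <- names(data$blocks)
  if (!"classifier" %in% names(grid))
    stop2("binary grids need a 'classifier' penalty column")
  pen_cols <- setdiff(names(grid), "classifier")
  folds <- kfold_split(n_subjects(data), K, seed,
                       stratify_labels = data$phenotype)
  metric <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pens <- stats::setNames(as.numeric(grid[g, pen_cols]), labs)
    vals <- numeric(K)
    for (k in seq_len(K)) {
      train <- subset_subjects(data, folds != k)
      test <- subset_subjects(data, folds == k)
      fit <- suppressMessages(suppressWarnings(
        run_hybrid(train, smcca_penalties = pens,
                   splsda_penalty = grid$classifier[g],
                   gamma1 = gamma1, gamma2 = gamma2, R = R,
                   scaling = scaling)))
      probs <- predict(fit, test)
      vals[k] <- classification_metrics(test$phenotype, probs)[[eval_method]]
    }
    metric[g] <- mean(vals)
  }
  tab <- cbind(grid, metric = metric)
  class(tab) <- "data.frame"
  names(tab)[names(tab) == "metric"] <- eval_method
  best <- pick_best(grid[, c(pen_cols, "classifier"), drop = FALSE],
                    metric, maximize = TRUE)
  structure(
    list(table = tab, best = best,
         best_penalties = stats::setNames(as.numeric(grid[best, pen_cols]), labs),
         best_classifier = grid$classifier[best],
         metric = eval_method, K = K, seed = seed),
    class = "cv_result"
  )
}

#' Automated scaling factors from preliminary pairwise correlations
#'
#' Sets each between-omics factor to the absolute preliminary canonical
#' correlation divided by the shrinkage parameter, and every
#' omics-phenotype factor to 1. Larger shrinkage de-emphasizes the
#' omics-omics terms relative to the phenotype terms.
#'
#' @param pairwise_cc a data.frame with columns `block_i`, `block_j`, `cc`
#'   (as returned by [pairwise_preliminary_cc()]), or a symmetric labelled
#'   matrix of correlations in `[-1, 1]`.
#' @param shrinkage positive divisor.
#' @return a [scaling_scheme()].
#' @export
auto_scaling_factors <- function(pairwise_cc, shrinkage) {
  if (shrinkage <= 0) stop2("shrinkage must be > 0")
  if (is.matrix(pairwise_cc)) {
    cc <- pairwise_cc
  } else {
    labs <- unique(c(pairwise_cc$block_i, pairwise_cc$block_j))
    cc <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
    for (k in seq_len(nrow(pairwise_cc))) {
      i <- pairwise_cc$block_i[k]
      j <- pairwise_cc$block_j[k]
      cc[i, j] <- cc[j, i] <- pairwise_cc$cc[k]
    }
  }
  if (any(abs(cc) > 1 + 1e-8)) stop2("correlations must lie in [-1, 1]")
  between <- abs(cc) / shrinkage
  diag(between) <- 0
  labs <- rownames(between)
  scaling_scheme(between, stats::setNames(rep(1, nrow(between)), labs))
}

#' Preliminary pairwise canonical correlations
#'
#' For every block pair, runs a two-block phenotype-free sparse CCA at a
#' stringent penalty and reports the achieved training canonical
#' correlation. These feed [auto_scaling_factors()].
#'
#' @param data a `multiomics` dataset with at least 2 blocks.
#' @param penalty stringent per-block penalty (default 0.1).
#' @return data.frame with columns `block_i`, `block_j`, `cc`.
#' @export
pairwise_preliminary_cc <- function(data, penalty = 0.1) {
  labs <- names(data$blocks)
  if (length(labs) < 2L) stop2("need at least 2 blocks")
  rows <- list()
  for (i in seq_len(length(labs) - 1L)) {
    for (j in (i + 1L):length(labs)) {
      pair <- data
      pair$blocks <- data$blocks[c(i, j)]
      fit <- suppressWarnings(
        solve_smcca(pair, penalties = penalty, include_phenotype = FALSE))
      cors <- suppressWarnings(score_correlations(pair, fit))
      cc <- cors$correlation[cors$block_j == labs[j]][1L]
      rows[[length(rows) + 1L]] <- data.frame(
        block_i = labs[i], block_j = labs[j], cc = cc,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Candidate scaling schemes on a phenotype-weight simplex
#'
#' Generates candidate schemes with all between-omics factors fixed at 1 and
#' the per-block phenotype factors taken from a simplex grid (step `step`,
#' summing to 1).
#'
#' @param labels block labels.
#' @param step grid step (default 0.1).
#' @return list of [scaling_scheme()] objects.
#' @export
candidate_scaling_schemes <- function(labels, step = 0.1) {
  T <- length(labels)
  units <- round(1 / step)
  combos <- compositions_of(units, T)
  lapply(seq_len(nrow(combos)), function(k) {
    between <- matrix(1, T, T, dimnames = list(labels, labels))
    diag(between) <- 0
    scaling_scheme(between, stats::setNames(combos[k, ] * step, labels))
  })
}

# All nonnegative integer T-tuples summing to n (deterministic order).
compositions_of <- function(n, T) {
  if (T == 1L) return(matrix(n, 1L, 1L))
  out <- list()
  for (first in 0:n) {
    rest <- compositions_of(n - first, T - 1L)
    out[[length(out) + 1L]] <- cbind(first, rest)
  }
  unname(do.call(rbind, out))
}

#' Nested search over scaling schemes and penalties
#'
#' Runs [cv_quantitative()] for every candidate scaling scheme and returns
#' the scheme (with its best penalties) minimizing the cross-validation
#' loss.
#'
#' @param data a `multiomics` dataset (quantitative phenotype).
#' @param candidate_schemes list of [scaling_scheme()] objects.
#' @param grid a penalty grid.
#' @param K,seed cross-validation controls.
#' @return list with `best_scheme`, `best_penalties`, `best_loss`,
#'   `cv_results` (per candidate).
#' @export
cv_scaling_search <- function(data, candidate_schemes, grid, K = 5L, seed = 1L) {
  if (length(candidate_schemes) < 1L) stop2("need at least one candidate scheme")
  results <- lapply(candidate_schemes, function(sc)
    cv_quantitative(data, grid, scaling = sc, K = K, seed = seed))
  losses <- vapply(results, function(r) r$table$loss[r$best], numeric(1))
  best <- which.min(losses)
  list(best_scheme = candidate_schemes[[best]],
       best_penalties = results[[best]]$best_penalties,
       best_loss = losses[best],
       cv_results = results)
}

#' Write a cross-validation table as TSV
#'
#' @param cv a `cv_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cv_table <- function(cv, path) {
  data.table::fwrite(cv$table, path, sep = "\t")
  invisible(path)
}
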