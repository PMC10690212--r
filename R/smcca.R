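# Sparse multiple canonical correlation analysis: block coordinate ascent on
# the weighted sum of pairwise cross-covariances under unit-L2 / L1 (LASSO)
# constraints, with a soft-threshold + bisection projection.

#' Project a vector onto the L1/L2 constraint set
#'
#' Returns `argmax_u v'u` subject to `||u||_2 <= 1` and `||u||_1 <= c`, the
#' penalized-matrix-decomposition update underlying each coordinate step.
#' The solution is a soft-thresholded, L2-normalized copy of `v`; the
#' threshold is located by bisection. At `c = 1` the solution concentrates on
#' the single largest-|v| coordinate (ties broken by lowest index).
#'
#' @param v numeric vector.
#' @param c L1 bound, `>= 1` (any unit-L2 vector has L1 norm at least 1).
#' @return numeric vector of `length(v)` with unit L2 norm, or all zeros
#'   (with attribute `zero = TRUE`) when `v` is the zero vector.
#' @export
l1_l2_project <- function(v, c) {
  v <- as.numeric(v)
  if (!is.finite(c) || c < 1) stop2("L1 bound c must be finite and >= 1")
  if (all(v == 0)) return(structure(v, zero = TRUE))
  if (c <= 1 + 1e-12) {
    u <- numeric(length(v))
    i <- which.max(abs(v))
    u[i] <- sign(v[i])
    return(u)
  }
  u <- v / sqrt(sum(v^2))
  if (sum(abs(u)) <= c) return(u)
  soft <- function(delta) {
    s <- sign(v) * pmax(abs(v) - delta, 0)
    ns <- sqrt(sum(s^2))
    if (ns > 0) s / ns else s
  }
  lo <- 0
  hi <- max(abs(v))
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (sum(abs(soft(mid))) > c) lo <- mid else hi <- mid
  }
  u <- soft(hi)                         # hi side guarantees the L1 bound
  if (sum(abs(u)) > c + 1e-6 || all(u == 0)) {
    # pathological exact ties: fall back to the feasible one-coordinate point
    u <- numeric(length(v))
    i <- which.max(abs(v))
    u[i] <- sign(v[i])
  }
  u
}

# Cross-product cache: C[[i]][[j]] = X_i' X_j (raw, no 1/(n-1) -- the scale
# cancels in the argmax), d[[i]] = X_i' Y.
cross_products <- function(blocks, y) {
  T <- length(blocks)
  C <- vector("list", T)
  for (i in seq_len(T)) C[[i]] <- vector("list", T)
  for (i in seq_len(T)) {
    for (j in seq_len(T)) {
      if (j > i) C[[i]][[j]] <- crossprod(blocks[[i]], blocks[[j]])
      else if (j < i) C[[i]][[j]] <- t(C[[j]][[i]])
    }
  }
  d <- lapply(blocks, function(b) drop(crossprod(b, y)))
  list(C = C, d = d)
}

#' Solve the sparse multiple CCA problem
#'
#' Maximizes `sum_{i<j} a_ij w_i' X_i' X_j w_j + sum_i b_i w_i' X_i' Y`
#' over per-block weight vectors with `||w_t||_2 = 1` and
#' `||w_t||_1 <= l_t * sqrt(p_t)`, by block coordinate ascent: each sweep
#' replaces `w_t` by the L1/L2 projection of its partial gradient. The
#' objective is non-decreasing across sweeps.
#'
#' @param data a `multiomics` dataset with column-standardized blocks.
#' @param penalties per-block sparsity fractions `l_t` in (0, 1] (recycled if
#'   scalar).
#' @param scaling a [scaling_scheme()], or `NULL` for the unweighted problem
#'   (all factors 1).
#' @param include_phenotype if `FALSE`, all phenotype factors are treated as
#'   0 (the phenotype-free filtering step of the binary hybrid).
#' @param max_iter,tol convergence controls: stop when the largest absolute
#'   weight change across blocks falls below `tol`, or after `max_iter`
#'   sweeps (returning the best iterate with `converged = FALSE`).
#' @param init_seed integer; only consulted if the deterministic
#'   cross-product initialization degenerates and a random restart is needed.
#' @return an object of class `canonical_weights`: list with `weights`
#'   (named list of unit-L2 per-block vectors under a deterministic sign
#'   convention), `objective`, `objective_trace`, `converged`, `iterations`.
#' @export
solve_smcca <- function(data, penalties, scaling = NULL,
                        include_phenotype = TRUE,
                        max_iter = 100L, tol = 1e-6, init_seed = 1L) {
  labs <- names(data$blocks)
  T <- length(labs)
  penalties <- check_penalties(penalties, labs)
  if (is.null(scaling)) scaling <- uniform_scaling(labs)
  if (!identical(rownames(scaling$between), labs))
    stop2("scaling scheme labels do not match the dataset's blocks")
  a <- scaling$between
  b <- scaling$pheno
  if (!include_phenotype) b[] <- 0
  y <- data$phenotype
  p <- block_sizes(data)
  cbound <- mapply(penalty_to_bound, penalties, p)
  cp <- cross_products(data$blocks, y)

  grad_t <- function(t, w) {
    g <- numeric(p[t])
    for (j in seq_len(T)) {
      if (j != t && a[t, j] > 0) g <- g + a[t, j] * drop(cp$C[[t]][[j]] %*% w[[j]])
    }
    if (b[t] > 0) g <- g + b[t] * cp$d[[t]]
    g
  }

  obj <- function(w) objective_core(cp, w, a, b)

  # deterministic initialization: row sums of the cross-product with the
  # first scaled partner block; phenotype cross-product or a uniform vector
  # as fallbacks; random restart only if everything above is exactly zero
  w <- vector("list", T)
  for (t in seq_len(T)) {
    partner <- which(a[t, ] > 0 & seq_len(T) != t)
    w0 <- if (length(partner) > 0) rowSums(cp$C[[t]][[partner[1L]]]) else numeric(p[t])
    if (all(w0 == 0) && b[t] > 0) w0 <- cp$d[[t]]
    if (all(w0 == 0)) w0 <- rep(1, p[t])
    if (all(w0 == 0)) w0 <- with_seed(init_seed, stats::rnorm(p[t]))
    w[[t]] <- l1_l2_project(w0, cbound[t])
  }
  names(w) <- labs

  trace <- numeric(0)
  converged <- FALSE
  zero_warned <- logical(T)
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    delta <- 0
    for (t in seq_len(T)) {
      g <- grad_t(t, w)
      if (max(abs(g)) < 1e-12) {
        if (!zero_warned[t]) {
          warn2("block '%s': zero gradient, weights set to 0", labs[t])
          zero_warned[t] <- TRUE
        }
        new_w <- numeric(p[t])
      } else {
        new_w <- l1_l2_project(g, cbound[t])
      }
      delta <- max(delta, max(abs(new_w - w[[t]])))
      w[[t]] <- new_w
    }
    trace <- c(trace, obj(w))
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warn2("coordinate ascent did not converge in %d sweeps (last change %.2e)",
          max_iter, delta)

  w <- lapply(w, canonical_sign)
  for (t in seq_len(T)) names(w[[t]]) <- colnames(data$blocks[[t]])
  structure(
    list(weights = w, objective = obj(w), objective_trace = trace,
         converged = converged, iterations = iterations,
         penalties = penalties, scaling = scaling,
         include_phenotype = include_phenotype),
    class = "canonical_weights"
  )
}

objective_core <- function(cp, w, a, b) {
  T <- length(w)
  val <- 0
  for (i in seq_len(T)) {
    for (j in seq_len(T)) {
      if (j > i && a[i, j] > 0)
        val <- val + a[i, j] * drop(crossprod(w[[i]], cp$C[[i]][[j]] %*% w[[j]]))
    }
    if (b[i] > 0) val <- val + b[[i]] * sum(w[[i]] * cp$d[[i]])
  }
  unname(val)
}

#' Evaluate the sparse multiple CCA objective
#'
#' Computes `sum_{i<j} a_ij w_i' X_i' X_j w_j + sum_i b_i w_i' X_i' Y` for
#' given weights (raw cross-products, no sample-size normalization).
#'
#' @param data a `multiomics` dataset.
#' @param weights a `canonical_weights` object or named list of per-block
#'   numeric vectors.
#' @param scaling a [scaling_scheme()] or `NULL` for all factors 1.
#' @param include_phenotype if `FALSE`, phenotype terms are dropped.
#' @return the objective value (numeric scalar).
#' @export
objective_value <- function(data, weights, scaling = NULL,
                            include_phenotype = TRUE) {
  w <- if (inherits(weights, "canonical_weights")) weights$weights else weights
  labs <- names(data$blocks)
  if (is.null(scaling)) scaling <- uniform_scaling(labs)
  b <- scaling$pheno
  if (!include_phenotype) b[] <- 0
  cp <- cross_products(data$blocks, data$phenotype)
  objective_core(cp, w[labs], scaling$between, b)
}

#' Correlations between block scores and the phenotype
#'
#' Forms the canonical scores `X_t w_t` and reports the Pearson correlation
#' for every block pair and between each block score and the phenotype.
#' Zero-variance scores yield correlation 0 with a warning.
#'
#' @param data a `multiomics` dataset.
#' @param weights a `canonical_weights` object or named list of vectors.
#' @return data.frame with columns `block_i`, `block_j` (block label or
#'   `"phenotype"`) and `correlation`.
#' @export
score_correlations <- function(data, weights) {
  w <- if (inherits(weights, "canonical_weights")) weights$weights else weights
  labs <- names(data$blocks)
  scores <- lapply(labs, function(l) drop(data$blocks[[l]] %*% w[[l]]))
  names(scores) <- labs
  n_degenerate <- 0L
  safe_cor <- function(u, v) {
    if (stats::sd(u) == 0 || stats::sd(v) == 0) {
      n_degenerate <<- n_degenerate + 1L
      return(0)
    }
    stats::cor(u, v)
  }
  rows <- list()
  if (length(labs) > 1) {
    for (i in seq_len(length(labs) - 1L)) {
      for (j in (i + 1L):length(labs)) {
        rows[[length(rows) + 1L]] <- data.frame(
          block_i = labs[i], block_j = labs[j],
          correlation = safe_cor(scores[[i]], scores[[j]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  for (i in seq_along(labs)) {
    rows[[length(rows) + 1L]] <- data.frame(
      block_i = labs[i], block_j = "phenotype",
      correlation = safe_cor(scores[[i]], data$phenotype),
      stringsAsFactors = FALSE)
  }
  if (n_degenerate > 0L)
    warn2("%d zero-variance score(s); correlation reported as 0", n_degenerate)
  do.call(rbind, rows)
}
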