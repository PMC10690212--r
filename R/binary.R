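# Binary-phenotype hybrid: phenotype-free sparse multiple CCA filtering,
# concatenated sparse PLS discriminant analysis, logistic aggregation of
# latent factors, and a gamma-weighted combination of the two weight sets.

code_labels <- function(labels) {
  u <- unique(labels)
  if (length(u) != 2L) stop2("binary labels must have exactly 2 distinct values, found %d", length(u))
  labs <- sort(as.character(u))         # lexicographically smaller label -> 0
  as.numeric(as.character(labels) == labs[2L])
}

#' Fit sparse PLS discriminant components
#'
#' Extracts `R` sparse partial-least-squares components against a binary
#' outcome: per component, the weight vector is the L1/L2 projection of
#' `X_deflated' y` (centered 0/1 labels) at bound `max(1, penalty*sqrt(p))`;
#' the data matrix is then deflated by regression on the component score
#' before the next extraction. Latent factors are `L = X Z` on the original
#' (undeflated) matrix.
#'
#' @param x numeric matrix, subjects x features, column-standardized.
#' @param labels binary vector (both classes present).
#' @param penalty sparsity fraction in (0, 1].
#' @param R number of components (default 3); reduced with a warning when it
#'   exceeds the rank of `x`.
#' @return an object of class `splsda_model`: list with `projection` (p x R),
#'   `latent` (n x R), `n_components`.
#' @export
splsda_fit <- function(x, labels, penalty, R = 3L) {
  x <- as.matrix(x)
  y01 <- code_labels(labels)
  if (penalty <= 0 || penalty > 1) stop2("splsda penalty must lie in (0, 1]")
  if (R < 1L) stop2("R must be >= 1")
  rk <- qr(x)$rank
  if (R > rk) {
    warn2("R = %d exceeds the data rank %d; reduced", R, rk)
    R <- rk
  }
  p <- ncol(x)
  cbound <- penalty_to_bound(penalty, p)
  yc <- y01 - mean(y01)
  Xd <- x
  Z <- matrix(0, p, R)
  for (r in seq_len(R)) {
    g <- drop(crossprod(Xd, yc))
    if (max(abs(g)) < 1e-12) {
      warn2("component %d: zero covariance with labels; stopping at %d component(s)", r, r - 1L)
      Z <- Z[, seq_len(r - 1L), drop = FALSE]
      R <- r - 1L
      break
    }
    wr <- l1_l2_project(g, cbound)
    Z[, r] <- wr
    tr <- drop(Xd %*% wr)
    Xd <- Xd - tr %*% crossprod(tr, Xd) / sum(tr^2)   # PLS1 deflation of X
  }
  if (R == 0L) stop2("no informative PLS component could be extracted")
  rownames(Z) <- colnames(x)
  L <- x %*% Z
  structure(list(projection = Z, latent = L, n_components = R),
            class = "splsda_model")
}

# Ridge-penalized IRLS for logistic regression (intercept unpenalized);
# fallback when plain IRLS diverges on separable latent factors.
ridge_logistic <- function(X, y, lambda = 1e-4, max_iter = 100L, tol = 1e-8) {
  Xi <- cbind(1, X)
  k <- ncol(Xi)
  beta <- numeric(k)
  pen <- diag(c(0, rep(lambda, k - 1L)), k)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xi %*% beta)
    mu <- stats::plogis(eta)
    wt <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / wt
    new_beta <- solve(crossprod(Xi, Xi * wt) + pen, crossprod(Xi, wt * z))
    new_beta <- drop(new_beta)
    if (max(abs(new_beta - beta)) < tol) {
      beta <- new_beta
      break
    }
    beta <- new_beta
  }
  beta
}

#' Aggregate latent factors into one axis by logistic regression
#'
#' Fits `logit(Y) = alpha_0 + alpha_1 r_1 + ... + alpha_R r_R` on the latent
#' factors of a [splsda_fit()] model and returns the slope coefficients. If
#' maximum likelihood diverges (perfect separation) or the design is
#' collinear, the fit is repeated with a small L2 penalty (1e-4) and the
#' fallback is logged.
#'
#' @param model a `splsda_model`.
#' @param labels binary vector.
#' @return list with `alpha` (length-R slopes), `intercept`, and `ridged`
#'   (logical flag for the penalized fallback).
#' @export
aggregate_latent <- function(model, labels) {
  L <- model$latent
  if (!all(is.finite(L))) stop2("latent factors contain non-finite values")
  y <- code_labels(labels)
  need_ridge <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, L), y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge|algorithm", conditionMessage(w)))
        need_ridge <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  coefs <- fit$coefficients
  if (!need_ridge && (!fit$converged || anyNA(coefs) || max(abs(coefs)) > 1e3))
    need_ridge <- TRUE
  if (need_ridge) {
    msg("logistic aggregation unstable (separation/collinearity); refitting with L2 penalty 1e-4")
    coefs <- ridge_logistic(L, y)
  }
  list(alpha = unname(coefs[-1L]), intercept = unname(coefs[1L]),
       ridged = need_ridge)
}

#' Combine CCA and discriminant weights
#'
#' Returns the convex combination
#' `W_t = (gamma1 * W~_t + gamma2 * W*_t) / (gamma1 + gamma2)` per block,
#' after normalizing each part to unit L2 norm and applying the package-wide
#' sign convention (largest-|entry| coordinate positive). Both steps are
#' no-ops for parts that already satisfy them; the sign convention makes the
#' combination invariant to binary label recoding (the discriminant part's
#' raw sign depends on which class is coded 1) and prevents the two parts
#' from cancelling for features they agree on.
#'
#' @param smcca_part,splsda_part named lists of per-block numeric vectors of
#'   matching lengths.
#' @param gamma1,gamma2 nonnegative weights for the omics-omics and
#'   omics-phenotype parts; `gamma1 + gamma2 > 0`.
#' @return named list of combined per-block vectors.
#' @export
combine_weights <- function(smcca_part, splsda_part, gamma1, gamma2) {
  if (gamma1 < 0 || gamma2 < 0 || gamma1 + gamma2 <= 0)
    stop2("gamma1, gamma2 must be >= 0 with a positive sum")
  stopifnot(identical(names(smcca_part), names(splsda_part)))
  Map(function(a, b) {
    if (length(a) != length(b)) stop2("per-block weight lengths differ")
    (gamma1 * canonical_sign(unit_l2(a)) + gamma2 * canonical_sign(unit_l2(b))) /
      (gamma1 + gamma2)
  }, smcca_part, splsda_part)
}

#' Run the hybrid algorithm for binary phenotypes
#'
#' Five stages: (1) phenotype-free sparse multiple CCA at relaxed penalties
#' filters features to those with omics-omics connections; (2) blocks are
#' subset to the surviving features; (3) the subsets are concatenated and
#' sparse PLS discriminant components are extracted against the labels;
#' (4) the latent factors are aggregated by logistic regression, giving
#' feature weights `W*_t = Z_t alpha`; (5) the CCA and discriminant weights
#' are combined as `(gamma1 W~_t + gamma2 W*_t)/(gamma1 + gamma2)`. Features
#' dropped in stage 1 keep combined weight 0. With a single block, stages
#' 1-2 are skipped and the result is the discriminant path alone.
#'
#' @param data a `multiomics` dataset with binary phenotype.
#' @param smcca_penalties stage-1 per-block penalties; the default 0.5 is
#'   deliberately relaxed so stage 1 keeps many features.
#' @param splsda_penalty stage-3 sparsity fraction in (0, 1].
#' @param gamma1,gamma2 combination weights (omics-omics vs omics-phenotype).
#' @param R number of PLS components (default 3).
#' @param scaling optional [scaling_scheme()] for stage 1.
#' @return an object of class `hybrid_weights`: list with `weights`
#'   (combined, full-length per block), `smcca_part`, `splsda_part`,
#'   `support` (per-block stage-1 indices), `alpha`, `intercept`,
#'   `projection`, `gamma1`, `gamma2`.
#' @export
run_hybrid <- function(data, smcca_penalties = 0.5, splsda_penalty,
                       gamma1 = 1, gamma2 = 1, R = 3L, scaling = NULL) {
  if (data$modality != "binary")
    stop2("run_hybrid requires a binary phenotype")
  labs <- names(data$blocks)
  T <- length(labs)
  p <- block_sizes(data)

  if (T == 1L) {
    support <- list(seq_len(p[1L]))
    names(support) <- labs
    smcca_w <- list(numeric(p[1L]))
    names(smcca_w) <- labs
    gamma1 <- 0
    gamma2 <- 1
  } else {
    s1 <- suppressWarnings(
      solve_smcca(data, penalties = smcca_penalties, scaling = scaling,
                  include_phenotype = FALSE))
    support <- lapply(s1$weights, function(w) which(w != 0))
    empty <- vapply(support, length, integer(1)) == 0L
    if (any(empty))
      stop2("stage 1 selected zero features in block(s) %s; use larger (more relaxed) penalties",
            paste(labs[empty], collapse = ", "))
    smcca_w <- s1$weights
    msg("stage 1 kept %s features per block",
        paste(vapply(support, length, integer(1)), collapse = "/"))
  }

  xsub <- do.call(cbind, Map(function(l, idx) {
    b <- data$blocks[[l]][, idx, drop = FALSE]
    colnames(b) <- paste(l, colnames(b), sep = ":")
    b
  }, labs, support))
  sub_sizes <- vapply(support, length, integer(1))

  model <- splsda_fit(xsub, data$phenotype, splsda_penalty, R = R)
  agg <- aggregate_latent(model, data$phenotype)
  wstar_sub <- drop(model$projection %*% agg$alpha)

  offsets <- c(0L, cumsum(sub_sizes))
  splsda_w <- vector("list", T)
  names(splsda_w) <- labs
  for (t in seq_len(T)) {
    full <- numeric(p[t])
    idx_sub <- (offsets[t] + 1L):offsets[t + 1L]
    full[support[[t]]] <- wstar_sub[idx_sub]
    names(full) <- colnames(data$blocks[[t]])
    splsda_w[[t]] <- full
  }

  combined <- combine_weights(smcca_w, splsda_w, gamma1, gamma2)
  structure(
    list(weights = combined, smcca_part = smcca_w, splsda_part = splsda_w,
         support = support, alpha = agg$alpha, intercept = agg$intercept,
         projection = model$projection, n_components = model$n_components,
         gamma1 = gamma1, gamma2 = gamma2),
    class = "hybrid_weights"
  )
}

#' Predict class probabilities from a hybrid fit
#'
#' Applies the stored sparse PLS projection and logistic aggregation to new
#' subjects: latent factors of the stage-1 feature subset are mapped through
#' `plogis(intercept + L alpha)`.
#'
#' @param object a `hybrid_weights` fit.
#' @param data a `multiomics` dataset with the same blocks/features as the
#'   training data.
#' @param ... unused.
#' @return numeric vector of predicted probabilities for the class coded 1.
#' @export
predict.hybrid_weights <- function(object, data, ...) {
  labs <- names(data$blocks)
  xsub <- do.call(cbind, Map(function(l, idx) data$blocks[[l]][, idx, drop = FALSE],
                             labs, object$support))
  L <- xsub %*% object$projection
  drop(stats::plogis(object$intercept + L %*% object$alpha))
}
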