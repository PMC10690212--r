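# Independent oracles used to verify the implementation. These deliberately
# use different algorithms from the package code paths.

# Exact L1/L2-constrained maximizer via sorted support segments: on each
# segment with fixed soft-threshold support the constraint ||u||_1 = c is a
# quadratic in the threshold, solved in closed form.
oracle_project_exact <- function(v, c) {
  a <- abs(v)
  u0 <- v / sqrt(sum(v^2))
  if (sum(abs(u0)) <= c) return(u0)
  ord <- order(a, decreasing = TRUE)
  as_u <- function(delta) {
    s <- sign(v) * pmax(a - delta, 0)
    s / sqrt(sum(s^2))
  }
  for (k in seq_along(a)) {
    top <- a[ord[seq_len(k)]]
    lo <- if (k < length(a)) a[ord[k + 1]] else 0
    hi <- top[k]
    A1 <- sum(top); A2 <- sum(top^2)
    qa <- k^2 - c^2 * k
    qb <- 2 * A1 * (c^2 - k)
    qc <- A1^2 - c^2 * A2
    disc <- qb^2 - 4 * qa * qc
    if (disc < 0) next
    for (root in (-qb + c(-1, 1) * sqrt(disc)) / (2 * qa)) {
      if (root >= lo - 1e-12 && root < hi) {
        u <- as_u(root)
        if (abs(sum(abs(u)) - c) < 1e-7) return(u)   # the binding threshold
      }
    }
  }
  u <- numeric(length(v))
  u[which.max(a)] <- sign(v[which.max(a)])
  u
}

# Feasible-grid search over soft thresholds (coarser, but fully brute force).
oracle_project_grid <- function(v, c, n_grid = 20000L) {
  deltas <- seq(0, max(abs(v)) * (1 - 1e-9), length.out = n_grid)
  best <- NULL
  best_val <- -Inf
  for (d in deltas) {
    s <- sign(v) * pmax(abs(v) - d, 0)
    ns <- sqrt(sum(s^2))
    if (ns == 0) next
    u <- s / ns
    if (sum(abs(u)) <= c + 1e-9 && sum(v * u) > best_val) {
      best_val <- sum(v * u)
      best <- u
    }
  }
  best
}

# Power-iteration PageRank on a weighted undirected graph; dangling nodes
# teleport uniformly.
oracle_pagerank_power <- function(A, damping = 0.85, tol = 1e-13) {
  n <- nrow(A)
  diag(A) <- 0
  deg <- rowSums(A)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) if (deg[i] > 0) P[i, ] <- A[i, ] / deg[i]
  dangling <- deg == 0
  r <- rep(1 / n, n)
  for (it in 1:10000) {
    r_new <- (1 - damping) / n +
      damping * (drop(crossprod(P, r)) + sum(r[dangling]) / n)
    if (max(abs(r_new - r)) < tol) return(r_new / sum(r_new))
    r <- r_new
  }
  r / sum(r)
}

# Exhaustive pairwise-concordance AUC.
oracle_auc_pairs <- function(y01, scores) {
  pos <- which(y01 == 1)
  neg <- which(y01 == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# NIPALS-style sparse PLS oracle: per component, exact-projected covariance
# direction, score on deflated matrix, X deflated by score regression;
# latent factors from the original matrix.
oracle_spls <- function(X, y01, penalty, R) {
  yc <- y01 - mean(y01)
  p <- ncol(X)
  cb <- max(1, penalty * sqrt(p))
  Xd <- X
  Z <- matrix(0, p, R)
  for (r in seq_len(R)) {
    g <- drop(crossprod(Xd, yc))
    w <- oracle_project_exact(g, cb)
    Z[, r] <- w
    tr <- drop(Xd %*% w)
    Xd <- Xd - outer(tr, drop(crossprod(tr, Xd))) / sum(tr^2)
  }
  list(projection = Z, latent = X %*% Z)
}

# Plain Newton/IRLS logistic regression oracle (no ridge).
oracle_irls_logistic <- function(X, y, max_iter = 200L, tol = 1e-12) {
  Xi <- cbind(1, X)
  beta <- numeric(ncol(Xi))
  for (it in seq_len(max_iter)) {
    eta <- drop(Xi %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    step <- solve(crossprod(Xi, Xi * W), crossprod(Xi, y - mu))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# Verbatim pruning-rule enumeration: rank by PageRank, summarize every size,
# then apply the m* / x / m_opt definitions directly.
oracle_prune_enumeration <- function(features, similarity, data, m1, m2,
                                     method = "pca") {
  S <- unclass(similarity)
  feats <- if (is.character(features)) match(features, colnames(S)) else features
  m2 <- min(m2, length(feats))
  adj <- S[feats, feats]
  pr <- pagerank_scores(adj)
  ranked <- feats[order(-pr, seq_along(pr))]
  allx <- do.call(cbind, lapply(names(data$blocks), function(l) {
    b <- data$blocks[[l]]
    colnames(b) <- paste(l, colnames(b), sep = ":")
    b
  }))
  y <- data$phenotype
  sizes <- m1:m2
  rho <- numeric(length(sizes))
  score_of <- list()
  for (s in seq_along(sizes)) {
    i <- sizes[s]
    idx <- ranked[1:i]
    summ <- if (method == "pca") pca_summarize(allx[, idx, drop = FALSE])
            else netshy_summarize(allx[, idx, drop = FALSE], S[idx, idx])
    rs <- apply(summ$scores, 2, function(v) if (sd(v) == 0) 0 else cor(v, y))
    k <- which.max(abs(rs))
    rho[s] <- rs[k]
    score_of[[s]] <- summ$scores[, k]
  }
  m_star <- sizes[which.max(abs(rho))]
  base <- score_of[[match(m_star, sizes)]]
  ok_x <- sizes[sizes >= m_star &
                vapply(seq_along(sizes), function(s)
                  sizes[s] >= m_star && abs(cor(base, score_of[[s]])) > 0.8,
                  logical(1))]
  x <- max(ok_x)
  cand <- sizes[sizes >= m_star & sizes <= x]
  keep <- abs(rho[match(cand, sizes)]) >= 0.9 * abs(rho[match(m_star, sizes)])
  list(m_star = m_star, x = x, m_opt = max(cand[keep]))
}
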