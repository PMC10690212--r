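# Fixture: module-style dataset where similarity mirrors feature correlation.
prune_fixture <- function(n = 60, p = c(15, 15), planted = c(5, 5), seed = 19,
                          n_subsamples = 10, penalties = 0.4) {
  gen <- generate_synthetic(synthetic_spec(n = n, p = p, planted = planted,
                                           seed = seed))
  d <- std_dataset(gen)
  sim <- suppressMessages(run_subsampling(
    d, penalties = penalties, fractions = 0.8,
    n_subsamples = n_subsamples, seed = seed))
  list(data = d, sim = sim, gen = gen)
}

test_that("PageRank matches the power-iteration oracle and sums to one", {
  # unweighted cycle: uniform by symmetry
  cyc <- matrix(0, 5, 5)
  for (i in 1:5) {
    cyc[i, i %% 5 + 1] <- 1
    cyc[i %% 5 + 1, i] <- 1
  }
  expect_equal(unname(pagerank_scores(cyc)), rep(0.2, 5), tolerance = 1e-9)

  # weighted 3-node path
  path <- matrix(c(0, 2, 0, 2, 0, 1, 0, 1, 0), 3, 3)
  expect_equal(unname(pagerank_scores(path)), oracle_pagerank_power(path),
               tolerance = 1e-8)

  # random weighted graphs up to 20 nodes, including isolated nodes
  set.seed(77)
  for (rep in 1:12) {
    n <- sample(3:20, 1)
    A <- matrix(runif(n * n), n, n) * (matrix(runif(n * n), n, n) < 0.4)
    A <- (A + t(A)) / 2
    diag(A) <- 0
    if (max(A) == 0) next
    pr <- pagerank_scores(A)
    expect_equal(sum(pr), 1, tolerance = 1e-9)
    expect_equal(unname(pr), oracle_pagerank_power(A), tolerance = 1e-8)
  }

  expect_warning(u <- pagerank_scores(matrix(0, 4, 4)), "all-zero")
  expect_equal(unname(u), rep(0.25, 4))
})

test_that("PCA summarization matches the eigen-decomposition oracle", {
  set.seed(23)
  x <- matrix(rnorm(6 * 4), 6, 4, dimnames = list(NULL, paste0("f", 1:4)))
  got <- pca_summarize(x)
  xs <- scale(x)
  eig <- eigen(cor(x))
  for (j in 1:3) {
    v <- eig$vectors[, j]
    v <- v * sign(v[which.max(abs(v))])
    expect_equal(unname(got$loadings[, j]), v, tolerance = 1e-8)
    expect_equal(unname(got$scores[, j]), drop(xs %*% v), tolerance = 1e-8)
  }
  # loadings orthonormal, scores centered
  expect_equal(crossprod(got$loadings), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(got$scores))), 1e-10)

  # rank-1 data: PC1 recovers the latent factor
  z <- rnorm(30)
  x1 <- outer(z, c(1, -2, 0.5, 3)) +
    matrix(rnorm(120, sd = 1e-6), 30, 4)
  colnames(x1) <- paste0("g", 1:4)
  s1 <- pca_summarize(x1)
  expect_gte(abs(cor(s1$scores[, 1], z)), 0.999)
})

test_that("NetSHy summarization equals the construct-then-PCA oracle", {
  set.seed(29)
  x <- matrix(rnorm(20 * 8), 20, 8, dimnames = list(NULL, paste0("f", 1:8)))
  A <- abs(outer(rnorm(8), rnorm(8)))
  A <- (A + t(A)) / 2
  diag(A) <- 0
  got <- netshy_summarize(x, A)

  # oracle: standardize, Laplacian of max-normalized adjacency, PCA on [X, XL]
  xs <- scale(x)
  An <- A / max(A)
  deg <- rowSums(An)
  Lp <- diag(as.numeric(deg > 0)) - outer(1 / sqrt(deg), 1 / sqrt(deg)) * An
  M <- cbind(xs, xs %*% Lp)
  eig <- eigen(cov(M))
  for (j in 1:3) {
    v <- eig$vectors[, j]
    v <- v * sign(v[which.max(abs(v))])
    expect_equal(unname(got$loadings[, j]), v, tolerance = 1e-8)
    expect_equal(unname(got$scores[, j]),
                 drop(scale(M, scale = FALSE) %*% v), tolerance = 1e-8)
  }

  # relabeling invariance: permuting features permutes loadings consistently
  perm <- c(5, 3, 8, 1, 2, 7, 4, 6)
  got_p <- netshy_summarize(x[, perm], A[perm, perm])
  expect_equal(abs(got_p$scores), abs(got$scores), tolerance = 1e-8)

  # edgeless module: PC1 score ranking identical to plain PCA
  got0 <- netshy_summarize(x, matrix(0, 8, 8))
  plain <- pca_summarize(x)
  expect_equal(order(got0$scores[, 1]), order(plain$scores[, 1]))
})

test_that("phenotype correlation picks the strongest component", {
  set.seed(31)
  sc <- matrix(rnorm(50 * 3), 50, 3)
  summ <- structure(list(scores = sc, loadings = diag(3), method = "pca"),
                    class = "summarization")
  got <- correlation_to_phenotype(summ, sc[, 2])
  expect_equal(got$which_pc, 2)
  expect_equal(got$rho, 1, tolerance = 1e-12)

  # independent phenotype at n = 200: weak correlation only
  sc2 <- matrix(rnorm(200 * 3), 200, 3)
  s2 <- structure(list(scores = sc2, loadings = diag(3), method = "pca"),
                  class = "summarization")
  got2 <- correlation_to_phenotype(s2, rnorm(200))
  expect_lt(abs(got2$rho), 0.25)

  # swapping binary coding negates rho, keeps the component
  y <- rbinom(50, 1, plogis(sc[, 1]))
  g1 <- correlation_to_phenotype(summ, y)
  g2 <- correlation_to_phenotype(summ, 1 - y)
  expect_equal(g1$rho, -g2$rho, tolerance = 1e-12)
  expect_equal(g1$which_pc, g2$which_pc)
})

test_that("pruning reproduces the verbatim enumeration oracle", {
  for (seed in c(19, 57)) {
    fx <- prune_fixture(seed = seed)
    feats <- colnames(fx$sim)   # whole 30-feature universe as one module
    for (method in c("pca", "netshy")) {
      got <- suppressWarnings(prune_network(feats, fx$sim, fx$data,
                                            m1 = 5, m2 = 25, method = method))
      oracle <- suppressWarnings(oracle_prune_enumeration(
        feats, fx$sim, fx$data, m1 = 5, m2 = 25, method = method))
      expect_equal(got$trace$m_star, oracle$m_star)
      expect_equal(got$trace$x, oracle$x)
      expect_equal(got$trace$m_opt, oracle$m_opt)
      # ordering and retention invariants
      tr <- got$trace
      expect_true(tr$m1 <= tr$m_star && tr$m_star <= tr$m_opt &&
                  tr$m_opt <= tr$x && tr$x <= tr$m2)
      expect_gte(abs(tr$rho_pheno[as.character(tr$m_opt)]),
                 0.9 * abs(tr$rho_pheno[as.character(tr$m_star)]) - 1e-12)
      expect_equal(length(got$features), tr$m_opt)
    }
  }
})

test_that("degenerate and redundant pruning ranges behave as decided", {
  fx <- prune_fixture()
  feats <- colnames(fx$sim)

  # m1 = m2 = module size returns the module whole
  got <- suppressWarnings(prune_network(feats, fx$sim, fx$data,
                                        m1 = length(feats), m2 = length(feats)))
  expect_equal(got$trace$m_star, length(feats))
  expect_equal(got$trace$m_opt, length(feats))
  expect_equal(sort(got$features), sort(feats))

  expect_error(prune_network(feats, fx$sim, fx$data, m1 = 99, m2 = 120),
               "exceeds")

  # redundant copies of signal features: correlations never drop, so the
  # search runs to the top of the range
  me <- micro_std()
  d <- me$data
  d$blocks$A <- d$blocks$A[, c(1, 2, 1, 2, 1, 2)]
  colnames(d$blocks$A) <- paste0("A_f", 1:6)
  d$blocks$B <- d$blocks$B[, c(1, 2), drop = FALSE]
  w <- list(A = rep(1 / sqrt(8), 6), B = rep(1 / sqrt(8), 2))
  sim <- accumulate_similarity(list(setNames(
    unlist(w), c(paste0("A:A_f", 1:6), paste0("B:B_f", 1:2)))))
  got2 <- suppressWarnings(prune_network(colnames(sim), sim, d,
                                         m1 = 2, m2 = 8, method = "pca"))
  expect_equal(got2$trace$x, 8)
  expect_equal(got2$trace$m_opt, 8)
})

test_that("module summary table has the expected schema", {
  fx <- prune_fixture()
  part <- suppressMessages(cluster_modules(fx$sim, cut_height = 0.995,
                                           min_size = 4))
  pruned <- lapply(part$modules, function(m)
    suppressWarnings(prune_network(m, fx$sim, fx$data, m1 = 4, m2 = 20)))
  tab <- module_summary_table(pruned, fx$data)
  expect_equal(names(tab), c("module", "size", "pc_correlation_to_phenotype",
                             "n_omics1", "n_omics2"))
  expect_equal(tab$size, tab$n_omics1 + tab$n_omics2)
  expect_equal(tab$module, seq_len(nrow(tab)))
  expect_true(all(abs(tab$pc_correlation_to_phenotype) <= 1))
})
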