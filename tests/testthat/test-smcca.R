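test_that("L1/L2 projection handles inactive, binding, and degenerate cases", {
  v <- c(3, -1, 2)
  # constraint inactive: plain normalization
  expect_equal(l1_l2_project(v, 10), v / sqrt(sum(v^2)))
  # c = 1: single coordinate at the max |v|, ties broken by lowest index
  expect_equal(l1_l2_project(c(2, -5, 1), 1), c(0, -1, 0))
  expect_equal(l1_l2_project(c(3, 3, 1), 1), c(1, 0, 0))
  # zero vector: flagged zero output
  z <- l1_l2_project(numeric(4), 2)
  expect_true(all(z == 0))
  expect_true(isTRUE(attr(z, "zero")))
})

test_that("L1/L2 projection matches independent oracles on random vectors", {
  set.seed(11)
  for (rep in 1:25) {
    v <- rnorm(10)
    c <- runif(1, 1.05, 2.8)
    u <- l1_l2_project(v, c)
    expect_lte(sum(abs(u)), c + 1e-6)
    expect_equal(sum(u^2), 1, tolerance = 1e-6)
    ue <- oracle_project_exact(v, c)
    expect_equal(u, ue, tolerance = 1e-6)
  }
  # brute-force grid oracle on one instance
  set.seed(3)
  v <- rnorm(10)
  u <- l1_l2_project(v, 1.5)
  ug <- oracle_project_grid(v, 1.5)
  expect_equal(sum(abs(u)), sum(abs(ug)), tolerance = 1e-4)
  expect_equal(u, ug, tolerance = 1e-3)
})

test_that("one-dimensional and duplicated-block cases behave as closed forms", {
  set.seed(21)
  z <- rnorm(30)
  xa <- matrix(z + rnorm(30, sd = 0.1), ncol = 1)
  xb <- matrix(z + rnorm(30, sd = 0.1), ncol = 1)
  d <- tiny_dataset(center_scale(xa), center_scale(xb), z)
  fit <- solve_smcca(d, penalties = 1)
  expect_equal(fit$weights$A, c(a1 = 1))
  expect_equal(fit$weights$B, c(b1 = 1))
  # objective = raw cross-product sum: a'b + a'y + b'y
  manual <- sum(d$blocks$A * d$blocks$B) + sum(d$blocks$A * d$phenotype) +
    sum(d$blocks$B * d$phenotype)
  expect_equal(fit$objective, manual, tolerance = 1e-10)

  # a block duplicated: scores correlate ~1 under relaxed penalties
  set.seed(22)
  x <- center_scale(matrix(rnorm(40 * 6), 40, 6))
  d2 <- tiny_dataset(x, x, rnorm(40))
  fit2 <- solve_smcca(d2, penalties = 1)
  cors <- score_correlations(d2, fit2)
  expect_gte(cors$correlation[cors$block_j == "B"], 0.999)
})

test_that("objective matches hand expansion and zero weights give zero", {
  xa <- matrix(c(1, -1, 0, 2, 0.5, -0.5), 3, 2, dimnames = list(NULL, c("a1", "a2")))
  xb <- matrix(c(0.5, 1, -1, 1, 2, 0), 3, 2, dimnames = list(NULL, c("b1", "b2")))
  y <- c(1, 0, -1)
  d <- tiny_dataset(xa, xb, y)
  w <- list(A = c(0.6, 0.8), B = c(1, 0))
  sc <- scaling_scheme(matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B"))),
                       c(A = 0.5, B = 1.5))
  manual <- 2 * drop(t(w$A) %*% crossprod(xa, xb) %*% w$B) +
    0.5 * sum((xa %*% w$A) * y) + 1.5 * sum((xb %*% w$B) * y)
  expect_equal(objective_value(d, w, sc), manual, tolerance = 1e-10)
  expect_equal(objective_value(d, list(A = c(0, 0), B = c(0, 0)), sc), 0)
  # unweighted two-block, no phenotype: w1' X1'X2 w2
  expect_equal(objective_value(d, w, include_phenotype = FALSE),
               drop(t(w$A) %*% crossprod(xa, xb) %*% w$B), tolerance = 1e-10)
})

test_that("coordinate ascent is monotone and scale-invariant in the factors", {
  me <- micro_std()
  d <- me$data
  fit <- solve_smcca(d, penalties = 0.8)
  expect_true(all(diff(fit$objective_trace) > -1e-8))
  expect_true(fit$converged)

  # multiplying all scaling factors by a constant leaves the argmax unchanged
  labs <- names(d$blocks)
  sc1 <- uniform_scaling(labs)
  sc7 <- scaling_scheme(sc1$between * 7, sc1$pheno * 7)
  f1 <- solve_smcca(d, penalties = 0.8, scaling = sc1)
  f7 <- solve_smcca(d, penalties = 0.8, scaling = sc7)
  expect_equal(f1$weights, f7$weights, tolerance = 1e-6)
  expect_equal(f7$objective, 7 * f1$objective, tolerance = 1e-6)
})

test_that("weights satisfy unit-norm and L1 constraints", {
  gen <- generate_synthetic(synthetic_spec(n = 60, p = c(15, 12), seed = 5))
  d <- std_dataset(gen)
  for (pen in c(0.2, 0.5, 0.9)) {
    fit <- solve_smcca(d, penalties = pen)
    for (lab in names(d$blocks)) {
      w <- fit$weights[[lab]]
      expect_equal(sum(w^2), 1, tolerance = 1e-8)
      expect_lte(sum(abs(w)), max(1, pen * sqrt(length(w))) + 1e-6)
    }
  }
})

test_that("planted features carry the weight mass in the zero-noise limit", {
  gen <- generate_synthetic(synthetic_spec(
    n = 100, p = c(20, 20), planted = c(5, 5), loading = 1, noise_sd = 0,
    seed = 33))
  d <- std_dataset(gen)
  fit <- solve_smcca(d, penalties = 0.4)
  for (lab in names(d$blocks)) {
    w <- fit$weights[[lab]]
    mass <- sum(w[gen$truth$planted[[lab]]]^2) / sum(w^2)
    expect_gte(mass, 0.95)
  }
})

test_that("single-omics quantitative path reduces to two-set sparse CCA", {
  set.seed(9)
  x <- center_scale(matrix(rnorm(50 * 8), 50, 8,
                           dimnames = list(NULL, paste0("f", 1:8))))
  y <- rnorm(50)
  d <- suppressMessages(multiomics_dataset(
    list(X = `rownames<-`(x, sprintf("s%02d", 1:50))),
    setNames(y, sprintf("s%02d", 1:50)), modality = "quantitative"))
  fit <- solve_smcca(d, penalties = 0.5)
  # two-set sparse CCA with a univariate second set: one projection of X'y
  expected <- l1_l2_project(drop(crossprod(x, y)), max(1, 0.5 * sqrt(8)))
  expected <- expected * sign(expected[which.max(abs(expected))])
  expect_equal(unname(fit$weights$X), unname(expected), tolerance = 1e-8)
})

test_that("score correlations handle degenerate and permuted phenotypes", {
  me <- micro_std()
  d <- me$data
  w <- list(A = c(1, 0, 0, 0), B = c(1, 0, 0, 0))
  cors <- score_correlations(d, w)
  expect_equal(cors$correlation[cors$block_j == "B"],
               cor(d$blocks$A[, 1], d$blocks$B[, 1]))

  # phenotype permuted: block-phenotype correlations near zero at n = 200
  gen <- generate_synthetic(synthetic_spec(n = 200, p = c(10, 10), seed = 14))
  d2 <- std_dataset(gen)
  d2$phenotype <- d2$phenotype[c(101:200, 1:100)]
  fit <- solve_smcca(d2, penalties = 0.6)
  cors2 <- score_correlations(d2, fit)
  expect_true(all(abs(cors2$correlation[cors2$block_j == "phenotype"]) < 0.2))

  # zero weights: zero-variance score reported as 0 with warning
  expect_warning(
    cors3 <- score_correlations(d, list(A = rep(0, 4), B = c(1, 0, 0, 0))),
    "zero-variance")
  expect_equal(cors3$correlation[1], 0)
})
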