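test_that("scaled prediction error follows its definition", {
  expect_equal(scaled_prediction_error(0.7, 0.7), 0)
  expect_equal(scaled_prediction_error(0.9, 0.45), 1.0)
  expect_equal(scaled_prediction_error(0.5, 0), Inf)
  expect_equal(scaled_prediction_error(-0.2, 0.4), 1.5)
})

test_that("penalty grids enumerate the full Cartesian product", {
  cand <- seq(0.1, 0.5, by = 0.1)
  g3 <- build_penalty_grid(list(Gene = cand, miRNA = cand, RPPA = cand))
  expect_equal(nrow(g3), 125)
  expect_equal(anyDuplicated(g3), 0)

  gb <- build_penalty_grid(list(Gene = cand, miRNA = cand, RPPA = cand),
                           classifier = cand)
  expect_equal(nrow(gb), 625)

  expect_equal(nrow(build_penalty_grid(list(X = 0.3))), 1)
  expect_error(build_penalty_grid(list(X = numeric(0))), "non-empty")
  expect_error(build_penalty_grid(list(X = c(0.2, 1.2))), "\\(0, 1\\]")
})

test_that("k-fold splits partition subjects with balanced folds", {
  f <- kfold_split(10, 5, seed = 4)
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(as.integer(table(f)), rep(2L, 5))
  expect_equal(f, kfold_split(10, 5, seed = 4))       # deterministic
  expect_false(identical(f, kfold_split(10, 5, seed = 5)))

  for (case in list(c(23, 4), c(17, 5), c(8, 8))) {
    fa <- kfold_split(case[1], case[2], seed = 1)
    expect_equal(length(fa), case[1])
    expect_lte(diff(range(table(factor(fa, levels = seq_len(case[2]))))), 1)
  }
  expect_error(kfold_split(5, 6, seed = 1), "K must satisfy")
})

test_that("stratified splits balance classes and reject impossible K", {
  y <- rep(c("case", "ctrl"), each = 6)
  f <- kfold_split(12, 3, seed = 2, stratify_labels = y)
  tab <- table(f, y)
  expect_true(all(tab == 2))
  expect_error(kfold_split(6, 5, seed = 1,
                           stratify_labels = c(1, 1, 1, 1, 1, 0)),
               "smaller K")
})

test_that("classification metrics match exhaustive pair counting", {
  # worked 4-subject case: pairs (0.9,0.6) (0.9,0.1) (0.4,0.1) concordant,
  # (0.4,0.6) discordant, no ties -> 3/4
  m <- classification_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))
  expect_equal(m[["auc"]], oracle_auc_pairs(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1)))
  expect_equal(m[["auc"]], 0.75)
  expect_equal(classification_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))[["auc"]], 1)
  expect_equal(classification_metrics(c(0, 1, 0, 1), rep(0.5, 4))[["auc"]], 0.5)

  set.seed(31)
  for (rep in 1:20) {
    n <- sample(6:50, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(runif(n), 2)             # rounding forces ties
    expect_equal(classification_metrics(y, s)[["auc"]],
                 oracle_auc_pairs(y, s), tolerance = 1e-12)
  }

  m2 <- classification_metrics(c(0, 0, 1, 1), c(0.2, 0.6, 0.7, 0.9))
  expect_equal(m2[["accuracy"]], 0.75)
  expect_equal(m2[["precision"]], 2 / 3)
  expect_equal(m2[["recall"]], 1)
  expect_equal(m2[["f1"]], 0.8)
  expect_error(classification_metrics(rep(1, 4), runif(4)), "2 distinct")
})

test_that("quantitative CV selects the signal-bearing penalty", {
  gen <- generate_synthetic(synthetic_spec(n = 80, p = c(15, 15),
                                           planted = c(4, 4), seed = 12))
  d <- std_dataset(gen)
  grid <- build_penalty_grid(list(omics1 = c(0.2, 0.6), omics2 = c(0.2, 0.6)))
  cv <- cv_quantitative(d, grid, K = 3, seed = 5)
  expect_equal(nrow(cv$table), 4)
  # internal consistency: stored loss equals the recomputed loss
  expect_equal(cv$table$loss,
               scaled_prediction_error(cv$table$train_cc, cv$table$test_cc))
  # winner minimizes the loss over the whole table
  expect_true(all(cv$table$loss[cv$best] <= cv$table$loss + 1e-12))
  # single-combination grid returns that combination
  g1 <- build_penalty_grid(list(omics1 = 0.3, omics2 = 0.3))
  cv1 <- cv_quantitative(d, g1, K = 3, seed = 5)
  expect_equal(cv1$best, 1L)
  expect_equal(unname(cv1$best_penalties), c(0.3, 0.3))
})

test_that("binary CV maximizes the chosen metric and validates inputs", {
  gen <- generate_synthetic(synthetic_spec(
    n = 60, p = c(10, 8), planted = c(4, 3), effect = 2,
    modality = "binary", seed = 44))
  d <- std_dataset(gen)
  grid <- build_penalty_grid(list(omics1 = 0.8, omics2 = 0.8),
                             classifier = c(0.6, 0.9))
  cv <- suppressMessages(cv_binary(d, grid, K = 3, seed = 2,
                                   eval_method = "auc"))
  expect_equal(nrow(cv$table), 2)
  expect_true(all(cv$table$auc[cv$best] >= cv$table$auc - 1e-12))
  expect_true(cv$best_classifier %in% c(0.6, 0.9))
  expect_error(cv_binary(d, grid, eval_method = "brier"),
               "accuracy, auc, precision, recall, f1")
})

test_that("binary CV on permuted labels stays near chance", {
  gen <- generate_synthetic(synthetic_spec(
    n = 100, p = c(10, 8), planted = c(3, 3), effect = 2,
    modality = "binary", seed = 91))
  d <- std_dataset(gen)
  d$phenotype <- with_seed_perm(d$phenotype, 7)
  grid <- build_penalty_grid(list(omics1 = 0.8, omics2 = 0.8),
                             classifier = 0.8)
  cv <- suppressMessages(cv_binary(d, grid, K = 4, seed = 3))
  expect_lt(abs(cv$table$auc[1] - 0.5), 0.15)
})

test_that("automated scaling factors reproduce the printed arithmetic", {
  one <- data.frame(block_i = "A", block_j = "B", cc = 0.8)
  sc <- auto_scaling_factors(one, shrinkage = 2)
  expect_equal(sc$between["A", "B"], 0.4)
  expect_equal(unname(sc$pheno), c(1, 1))

  three <- data.frame(block_i = c("Gene", "Gene", "RPPA"),
                      block_j = c("miRNA", "RPPA", "miRNA"),
                      cc = c(0.960, 0.689, 0.632))
  sc5 <- auto_scaling_factors(three, shrinkage = 5)
  expect_equal(round(sc5$between["Gene", "miRNA"], 3), 0.192)
  expect_equal(round(sc5$between["Gene", "RPPA"], 3), 0.138)
  expect_equal(round(sc5$between["RPPA", "miRNA"], 3), 0.126)

  # identity shrinkage returns |cc| unchanged; invalid shrinkage errors
  expect_equal(auto_scaling_factors(one, 1)$between["A", "B"], 0.8)
  expect_error(auto_scaling_factors(one, 0), "shrinkage")
})

test_that("preliminary pairwise correlations behave at the extremes", {
  set.seed(8)
  x <- center_scale(matrix(rnorm(50 * 8), 50, 8))
  d_dup <- tiny_dataset(x, x, rnorm(50))
  cc_dup <- pairwise_preliminary_cc(d_dup)
  expect_gte(cc_dup$cc, 0.999)

  gen <- generate_synthetic(synthetic_spec(n = 200, p = c(20, 20),
                                           planted = c(0, 0), seed = 3))
  d_null <- std_dataset(gen)
  cc_null <- pairwise_preliminary_cc(d_null)
  expect_lt(abs(cc_null$cc), 0.5)

  # symmetric in block order
  d_rev <- d_null
  d_rev$blocks <- rev(d_rev$blocks)
  expect_equal(pairwise_preliminary_cc(d_rev)$cc, cc_null$cc, tolerance = 1e-8)
})

test_that("scaling-scheme search favors the phenotype-bearing block", {
  schemes <- candidate_scaling_schemes(c("omics1", "omics2"), step = 0.5)
  sums <- vapply(schemes, function(s) sum(s$pheno), numeric(1))
  expect_true(all(abs(sums - 1) < 1e-10))

  # omics1 carries phenotype signal, omics2 is connected but phenotype-free
  gen <- generate_synthetic(synthetic_spec(n = 80, p = c(12, 12),
                                           planted = c(4, 4), seed = 21))
  d <- std_dataset(gen)
  d$blocks$omics2 <- center_scale(matrix(
    rnorm(80 * 12), 80, 12,
    dimnames = dimnames(d$blocks$omics2)))
  grid <- build_penalty_grid(list(omics1 = 0.4, omics2 = 0.4))
  got <- cv_scaling_search(d, schemes, grid, K = 3, seed = 6)
  expect_gte(got$best_scheme$pheno[["omics1"]],
             got$best_scheme$pheno[["omics2"]])
  single <- cv_scaling_search(d, schemes[2], grid, K = 3, seed = 6)
  expect_equal(single$best_scheme, schemes[[2]])
})
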