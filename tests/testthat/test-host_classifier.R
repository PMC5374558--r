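test_that("rank AUC matches the enumerated pair count and conventions", {
  expect_equal(auc(c(0.9, 0.8), c(0.85, 0.1)), 0.75)
  expect_equal(auc(rep(0.5, 4), rep(0.5, 3)), 0.5) # all ties
  expect_equal(auc(c(3, 4), c(1, 2)), 1)
  expect_error(auc(numeric(0), 1), "non-empty")
})

test_that("rank AUC is invariant under monotone transforms and complements", {
  set.seed(7)
  for (i in 1:10) {
    p <- rnorm(15); n <- rnorm(12)
    a <- auc(p, n)
    expect_equal(auc(exp(p), exp(n)), a, tolerance = 1e-12)
    expect_equal(auc(qnorm(pnorm(p)), qnorm(pnorm(n))), a, tolerance = 1e-9)
    expect_equal(a + auc(n, p), 1, tolerance = 1e-12) # tie-free complement
    expect_equal(a, trapezoid_auc(p, n), tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  p <- round(runif(20), 2); n <- round(runif(25), 2)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 20), rep(0, 25)), predictor = c(p, n),
    direction = "<", quiet = TRUE)))
  expect_equal(auc(p, n), ref, tolerance = 1e-12)
})

test_that("negative resampling draws disjoint seeded sets", {
  pool <- paste0("n", 1:12)
  sets <- sample_negative_sets(pool, 4, 3, repeats = 10, seed = 42)
  for (s in sets) {
    expect_length(s$train, 4)
    expect_length(s$test, 3)
    expect_length(intersect(s$train, s$test), 0)
    expect_true(all(c(s$train, s$test) %in% pool))
  }
  # exhaustive draw partitions the pool
  full <- sample_negative_sets(pool, 7, 5, repeats = 3, seed = 1)
  expect_setequal(c(full[[1]]$train, full[[1]]$test), pool)
  # reproducible under seed, different across seeds
  expect_identical(sets, sample_negative_sets(pool, 4, 3, 10, seed = 42))
  expect_false(identical(sets, sample_negative_sets(pool, 4, 3, 10, seed = 43)))
  expect_error(sample_negative_sets(pool, 10, 5, 2, 1), "too small")
})

test_that("every learner orders a separable toy problem correctly", {
  set.seed(10)
  x <- rbind(matrix(rnorm(20 * 4, mean = 2), 20, 4),
             matrix(rnorm(20 * 4, mean = -2), 20, 4))
  colnames(x) <- paste0("w", 1:4)
  y <- rep(c(1, 0), each = 20)
  for (kind in c("logistic_l1", "svm_rbf", "random_forest",
                 "gaussian_nb", "bernoulli_nb")) {
    m <- train_model(x, y, learner_spec(kind, seed = 3))
    s <- predict_scores(m, x)
    expect_true(all(is.finite(s)), info = kind)
    expect_gt(min(s[y == 1]), max(s[y == 0]))
    if (kind != "svm_rbf") {
      expect_true(all(s >= 0 & s <= 1), info = kind)
    }
    # scores depend only on their own row
    expect_equal(predict_scores(m, x[c(3, 1), ]), s[c(3, 1)],
                 tolerance = 1e-12, info = kind)
  }
  expect_error(train_model(x, rep(1, 40), learner_spec()), "single class")
  x_bad <- x; x_bad[1, 1] <- NaN
  expect_error(train_model(x_bad, y, learner_spec()), "non-finite")
})

test_that("contradictory duplicated examples score one half under logistic", {
  # two distinct points, each appearing once with label 1 and once with 0:
  # the symmetric likelihood is maximized at beta = 0, so every score is 1/2
  x <- rbind(c(0, 0), c(1, 1), c(0, 0), c(1, 1))
  y <- c(1, 0, 0, 1)
  # glmnet warns about the (deliberately) tiny sample
  m <- suppressWarnings(train_model(x, y, learner_spec("logistic_l1")))
  expect_equal(predict_scores(m, x), rep(0.5, 4), tolerance = 1e-6)
})

test_that("forest training is deterministic under a fixed seed", {
  set.seed(1)
  x <- matrix(rnorm(30 * 5), 30, 5)
  y <- rep(c(1, 0), 15)
  m1 <- train_model(x, y, learner_spec("random_forest", ntree = 1, seed = 99))
  m2 <- train_model(x, y, learner_spec("random_forest", ntree = 1, seed = 99))
  expect_identical(predict_scores(m1, x), predict_scores(m2, x))
})

test_that("models survive serialization with bit-identical predictions", {
  set.seed(2)
  x <- matrix(rnorm(20 * 6), 20, 6)
  colnames(x) <- paste0("w", 1:6)
  y <- rep(c(1, 0), each = 10)
  for (kind in c("logistic_l1", "random_forest", "gaussian_nb")) {
    m <- train_model(x, y, learner_spec(kind, seed = 5))
    f <- tempfile(fileext = ".rds")
    saveRDS(m, f)
    expect_identical(predict_scores(readRDS(f), x), predict_scores(m, x))
  }
})

test_that("recipe mismatches are refused with both recipes named", {
  rec <- small_bench()$records
  f1 <- feature_matrix(rec, "F1", k = 2)
  f2 <- feature_matrix(rec, "F2", k = 2, order = 1)
  m <- train_model(f1, as.integer(rec$host_genus == "Host01"))
  expect_error(predict_scores(m, f2), "F1.*F2")
  expect_length(predict_scores(m, f1[0, , drop = FALSE]), 0)
})

test_that("the evaluation protocol is reproducible and self-consistent", {
  bench <- small_bench()
  part <- partition_by_cutting_year(bench$records, "Host01", 2010)
  feats <- feature_matrix(bench$records, "F1", k = 3)
  r1 <- evaluate_host(bench$records, part, learner = learner_spec("random_forest"),
                      repeats = 3, seed = 9, features = feats)
  r2 <- evaluate_host(bench$records, part, learner = learner_spec("random_forest"),
                      repeats = 3, seed = 9, features = feats)
  expect_identical(r1$auc, r2$auc)
  expect_length(r1$auc, 3)
  expect_true(all(r1$auc >= 0 & r1$auc <= 1))
  expect_equal(r1$mean_auc, mean(r1$auc))
  expect_equal(r1$sd_auc, sd(r1$auc))
  # divergent hosts separate essentially perfectly even at this small scale
  expect_gt(r1$mean_auc, 0.95)
  # single repeat: SD reported as 0 and flagged
  r3 <- evaluate_host(bench$records, part, repeats = 1, seed = 9,
                      features = feats)
  expect_equal(r3$sd_auc, 0)
  expect_true(r3$degenerate_sd)
})
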