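test_that("the 4:1 split produces the expected sizes", {
  s <- split_cohort(524, seed = 1)
  expect_length(s$train, 419L)
  expect_length(s$test, 105L)
  expect_identical(sort(c(s$train, s$test)), 1:524)
  s5 <- split_cohort(5, seed = 1)
  expect_length(s5$train, 4L)
  expect_length(s5$test, 1L)
  expect_identical(split_cohort(100, seed = 3), split_cohort(100, seed = 3))
  expect_false(identical(split_cohort(100, seed = 3)$train,
                         split_cohort(100, seed = 4)$train))
  expect_error(split_cohort(4), "at least 5")
})

test_that("grouped splits keep every patient on one side", {
  groups <- rep(1:40, each = 3)
  s <- split_cohort(120, seed = 2, groups = groups)
  expect_length(intersect(unique(groups[s$train]), unique(groups[s$test])), 0L)
  expect_identical(sort(c(s$train, s$test)), 1:120)
})

test_that("average precision matches hand-computed and baseline values", {
  expect_equal(auprc(c(0.1, 0.2, 0.9, 0.8), c(0, 0, 1, 1)), 1)
  # reversed ranking: AP = 1/2*1/3 + 1/2*1/2 = 5/12
  expect_equal(auprc(c(0.9, 0.8, 0.3, 0.1), c(0, 0, 1, 1)), 5 / 12)
  set.seed(6)
  n <- 1e4
  y <- rep(c(0, 1), n / 2)
  expect_lt(abs(auprc(stats::runif(n), y) - 0.5), 0.02)
  expect_error(auprc(runif(5), rep(1, 5)), "classes")
})

test_that("the nested objective tracks separability and is deterministic", {
  sf <- synthetic_feature_table(n = 120, p_noise = 6, seed = 3)
  p <- trial_params(n_features = 2, nrounds = 30, max_depth = 3, eta = 0.2,
                    weight = 1)
  o1 <- trial_objective(sf$table, sf$labels, p, seed = 5)
  o2 <- trial_objective(sf$table, sf$labels, p, seed = 5)
  expect_identical(o1, o2)
  expect_gt(o1$objective, 0.9)
  # the informative feature leads the aggregated selection
  expect_true("signal1" %in% o1$features)

  # pure noise: objective near the positive prevalence
  set.seed(8)
  n <- 300
  y <- rep(c(0L, 1L), n / 2)
  noise <- as.data.frame(matrix(stats::rnorm(n * 8), n,
                                dimnames = list(NULL, paste0("v", 1:8))))
  on <- trial_objective(noise, y, trial_params(3, 20, 3, 0.2, 1), seed = 5)
  expect_lt(abs(on$objective - 0.5), 0.1)
  expect_error(trial_objective(noise, y, trial_params(50, 20, 3, 0.2, 1)),
               "exceeds")
})

test_that("optimization is reproducible and beats or ties any single trial", {
  sf <- synthetic_feature_table(n = 100, p_noise = 5, seed = 4)
  o1 <- optimize_model(sf$table, sf$labels, budget = 4, seed = 2)
  o2 <- optimize_model(sf$table, sf$labels, budget = 4, seed = 2)
  expect_identical(o1$best_params, o2$best_params)
  expect_identical(o1$trace$objective, o2$trace$objective)
  expect_equal(o1$model$objective, max(o1$trace$objective))
  expect_identical(o1$model$features,
                   dlmvoi:::stage1_features(sf$table, sf$labels,
                                            o1$best_params$n_features, 10, 2))
  b1 <- optimize_model(sf$table, sf$labels, budget = 1, seed = 9)
  expect_identical(b1$best_params, b1$model$params)
})

test_that("the class-weight search is centered on the training imbalance ratio", {
  set.seed(10)
  y <- c(rep(1L, 155), rep(0L, 264))
  tab <- data.frame(f1 = y + stats::rnorm(419, 0, 0.8),
                    f2 = stats::rnorm(419))
  o <- optimize_model(tab, y, budget = 2, seed = 1)
  expect_equal(o$model$class_ratio, 264 / 155)
  expect_true(all(o$trace$weight >= 264 / 155 / 2 - 1e-9))
  expect_true(all(o$trace$weight <= 2 * 264 / 155 + 1e-9))
})

test_that("prediction is deterministic, row-wise, and demands its features", {
  sf <- synthetic_feature_table(n = 80, p_noise = 4, seed = 6)
  o <- optimize_model(sf$table, sf$labels, budget = 2, seed = 3)
  sc1 <- predict(o$model, sf$table)
  sc2 <- predict(o$model, sf$table)
  expect_identical(sc1, sc2)
  expect_true(all(sc1 >= 0 & sc1 <= 1))
  perm <- sample(nrow(sf$table))
  expect_equal(predict(o$model, sf$table[perm, ]), sc1[perm])
  expect_error(predict(o$model, sf$table[, "noise1", drop = FALSE]),
               "missing feature")
  # training rows of a separable problem are ranked near-perfectly
  expect_gt(auprc(sc1, sf$labels), 0.95)
})

test_that("optimization never sees held-out rows", {
  sf <- synthetic_feature_table(n = 100, p_noise = 4, seed = 12)
  sp <- split_cohort(100, seed = 1)
  train <- sf$table[sp$train, ]
  ytr <- sf$labels[sp$train]
  o1 <- optimize_model(train, ytr, budget = 2, seed = 4)
  # corrupting the held-out rows cannot change the fitted model
  corrupted <- sf$table
  corrupted[sp$test, ] <- 1e6
  o2 <- optimize_model(corrupted[sp$train, ], ytr, budget = 2, seed = 4)
  expect_identical(o1$best_params, o2$best_params)
  expect_identical(predict(o1$model, sf$table[sp$test, ]),
                   predict(o2$model, sf$table[sp$test, ]))
})
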