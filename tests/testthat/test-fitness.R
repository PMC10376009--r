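test_that("the weighted cost matches direct arithmetic", {
  expect_equal(wrapper_cost(1.0, 1, 100), 0.0001, tolerance = 1e-15)
  expect_equal(wrapper_cost(0, 100, 100), 1.0, tolerance = 1e-15)
  # published operating point: 96.79% accuracy with 562 of 2048 features
  expect_equal(wrapper_cost(0.9679, 562, 2048), 0.034523140625, tolerance = 1e-12)
  expect_error(wrapper_cost(0.5, 0, 10), "at least 1")
})

test_that("cost is monotone in feature count and accuracy", {
  cfg <- cost_config(0.99, 0.01)
  costs_by_n <- wrapper_cost(0.9, 1:50, 50, cfg)
  expect_true(all(diff(costs_by_n) > 0))
  accs <- seq(0, 1, by = 0.05)
  costs_by_acc <- wrapper_cost(accs, 10, 50, cfg)
  expect_true(all(diff(costs_by_acc) < 0))
})

test_that("stratified holdout rounds per class and is seed-deterministic", {
  lab <- rep(c("benign", "malignant", "normal"), c(437, 210, 133))
  sp <- stratified_holdout(lab, 0.2, seed = 11)
  expect_equal(as.vector(table(lab[sp$test_indices])), c(87, 42, 27))
  expect_length(sp$train_indices, 624)
  expect_length(sp$test_indices, 156)
  expect_length(intersect(sp$train_indices, sp$test_indices), 0)
  expect_setequal(c(sp$train_indices, sp$test_indices), seq_along(lab))
  sp2 <- stratified_holdout(lab, 0.2, seed = 11)
  expect_identical(sp, sp2)
  expect_false(identical(sp$test_indices,
                         stratified_holdout(lab, 0.2, seed = 12)$test_indices))
})

test_that("tiny classes split to one train and one test sample", {
  sp <- stratified_holdout(c("A", "A", "B", "B"), 0.5, seed = 1)
  expect_length(sp$test_indices, 2)
  expect_error(stratified_holdout(c("A", "B", "B"), 0.5), "fewer than 2")
})

test_that("a perfectly separating feature yields holdout accuracy 1", {
  n <- 40
  lab <- rep(c("a", "b"), each = n / 2)
  set.seed(2)
  X <- cbind(ifelse(lab == "a", -5, 5) + rnorm(n, sd = 0.1),
             matrix(rnorm(n * 4), n, 4))
  tab <- feature_table(X, lab)
  sp <- stratified_holdout(lab, 0.25, seed = 2)
  fit <- evaluate_mask(tab, sp, c(1, 0, 0, 0, 0))
  expect_equal(fit$accuracy, 1.0)
  expect_equal(fit$n_selected, 1L)
  expect_equal(fit$cost, wrapper_cost(1, 1, 5))
})

test_that("mask evaluation is deterministic and handles edge masks", {
  fx <- make_fixture(seed = 6)
  mask <- rep(c(1L, 0L), 15)
  f1 <- evaluate_mask(fx$table, fx$split, mask)
  f2 <- evaluate_mask(fx$table, fx$split, mask)
  expect_identical(f1, f2)
  expect_error(evaluate_mask(fx$table, fx$split, rep(0L, 30)), "empty subset")
  expect_error(evaluate_mask(fx$table, fx$split, rep(1L, 10)), "length")
  # all-ones mask reproduces the unmasked full-feature fit
  full <- evaluate_mask(fx$table, fx$split, rep(1L, 30))
  expect_equal(full$n_selected, 30L)
  expect_equal(full$cost, wrapper_cost(full$accuracy, 30, 30))
})

test_that("constant feature columns standardize to zero without error", {
  lab <- rep(c("a", "b"), each = 10)
  set.seed(3)
  X <- cbind(rep(1, 20), ifelse(lab == "a", -2, 2) + rnorm(20, sd = 0.1))
  tab <- feature_table(X, lab)
  sp <- stratified_holdout(lab, 0.2, seed = 3)
  fit <- evaluate_mask(tab, sp, c(1L, 1L))
  expect_equal(fit$accuracy, 1.0)
})

test_that("the fitness cache avoids refitting duplicate masks", {
  fx <- make_fixture(seed = 8)
  f <- make_fitness(fx$table, fx$split)
  mask <- rep(c(1L, 0L, 1L), 10)
  r1 <- f(mask)
  r2 <- f(mask)
  expect_identical(r1, r2)
  expect_equal(fitness_stats(f)$calls, 2L)
  expect_equal(fitness_stats(f)$fits, 1L)
  f(rep(1L, 30))
  expect_equal(fitness_stats(f)$fits, 2L)

  f_nc <- make_fitness(fx$table, fx$split, settings = svm_settings(cache = FALSE))
  f_nc(mask); f_nc(mask)
  expect_equal(fitness_stats(f_nc)$fits, 2L)
})
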