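test_that("binarization uses a strict threshold and repair fills empty masks", {
  expect_identical(binarize(c(0.2, 0.7, 0.5), 0.5), c(0L, 1L, 0L))
  expect_identical(binarize(rep(1, 4)), rep(1L, 4))
  expect_identical(binarize(rep(0, 4)), rep(0L, 4))
  expect_identical(repair_mask(c(0L, 1L, 0L)), c(0L, 1L, 0L))
  set.seed(5); m1 <- repair_mask(rep(0L, 8))
  set.seed(5); m2 <- repair_mask(rep(0L, 8))
  expect_equal(sum(m1), 1L)
  expect_identical(m1, m2)
})

test_that("unknown algorithm names list the ten valid schemes", {
  err <- tryCatch(optimizer_config("simulated-annealing"), error = identity)
  expect_s3_class(err, "error")
  for (alg in optimizer_algorithms()) {
    expect_match(conditionMessage(err), alg)
  }
})

test_that("every scheme is elitist, bounded and seed-deterministic", {
  # bounds asserted inside the objective: every evaluated point must be in the box
  sphere_checked <- function(x) {
    expect_true(all(x >= 0 & x <= 1))
    sum(x^2)
  }
  for (alg in optimizer_algorithms()) {
    for (seed in 1:3) {
      cfg <- optimizer_config(alg, population_size = 6, max_iterations = 25,
                              seed = seed)
      r1 <- optimize_continuous(sphere_checked, 8, cfg)
      expect_true(all(diff(r1$trace$best_cost) <= 0),
                  info = sprintf("%s seed %d not monotone", alg, seed))
      expect_true(all(r1$best_position >= 0 & r1$best_position <= 1))
      r2 <- optimize_continuous(sphere_checked, 8, cfg)
      expect_identical(r1$trace, r2$trace,
                       label = sprintf("%s seed %d trace", alg, seed))
      expect_identical(r1$best_position, r2$best_position)
    }
  }
})

test_that("iterating improves on the initial population", {
  f <- benchmark_function("sphere")
  for (alg in optimizer_algorithms()) {
    long <- optimize_continuous(f, 10, optimizer_config(alg, seed = 2))
    expect_lt(long$trace$best_cost[100], long$trace$best_cost[1])
  }
})

test_that("optimizer runs never evaluate an empty mask and reduce features", {
  fx <- make_fixture(n = c(8L, 8L), d = 6L, k = 2L, seed = 3)
  for (alg in optimizer_algorithms()) {
    # would error "empty subset" if repair ever failed
    res <- run_optimizer(fx$table, fx$split, cost_config(),
                         optimizer_config(alg, population_size = 4,
                                          max_iterations = 6, seed = 1))
    expect_gte(res$n_selected, 1L)
    expect_equal(res$n_selected, sum(res$best_mask))
    expect_equal(res$best_cost,
                 wrapper_cost(res$best_accuracy, res$n_selected, res$n_total))
  }
})

test_that("degenerate budgets still return a valid result", {
  fx <- make_fixture(n = c(6L, 6L), d = 5L, k = 2L, seed = 4)
  res <- run_optimizer(fx$table, fx$split, cost_config(),
                       optimizer_config("eo", population_size = 2,
                                        max_iterations = 1, seed = 9))
  expect_s3_class(res, "selection_result")
  expect_equal(nrow(res$trace), 1L)
  expect_length(res$best_mask, 5L)
})

test_that("binary runs are reproducible end to end", {
  fx <- make_fixture(seed = 10)
  cfg <- optimizer_config("mpa", max_iterations = 10, seed = 42)
  r1 <- run_optimizer(fx$table, fx$split, cost_config(), cfg)
  r2 <- run_optimizer(fx$table, fx$split, cost_config(), cfg)
  expect_identical(r1$best_mask, r2$best_mask)
  expect_identical(r1$trace, r2$trace)
})

test_that("selection pressure strictly reduces the feature set", {
  # gamma-term pressure: across seeds the best mask is smaller than d
  fx <- make_fixture(seed = 12)
  for (seed in 1:5) {
    res <- run_optimizer(fx$table, fx$split, cost_config(),
                         optimizer_config("eo", max_iterations = 15, seed = seed))
    expect_lt(res$n_selected, res$n_total)
  }
})
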