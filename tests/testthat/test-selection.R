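summaries_from_reference <- function() {
  ref <- eo_reported_accuracy()
  lapply(seq_len(nrow(ref)), function(i) {
    network_run_summary(ref$backbone[i], "eo", ref$accuracy_pct[i])
  })
}

test_that("the strict 94% rule keeps exactly the two top backbones", {
  sel <- select_networks(summaries_from_reference(), 94)
  expect_identical(sel, c("ResNet-50", "Inception-ResNet-v2"))
  expect_length(select_networks(summaries_from_reference(), 99), 0)
})

test_that("the threshold comparison is strict and order-independent", {
  at_bar <- list(network_run_summary("NetA", "eo", 94.0),
                 network_run_summary("NetB", "eo", 94.1))
  expect_identical(select_networks(at_bar, 94), "NetB")
  shuffled <- summaries_from_reference()[c(16:1)]
  expect_identical(select_networks(shuffled, 94),
                   select_networks(summaries_from_reference(), 94))
  # idempotence: reapplying to the already-selected set changes nothing
  sel <- select_networks(summaries_from_reference(), 94)
  kept <- Filter(function(s) s$backbone %in% sel, summaries_from_reference())
  expect_identical(select_networks(kept, 94), sel)
})

test_that("concatenation sums selected widths and keeps provenance", {
  lab <- rep(c("a", "b", "c"), each = 10)
  set.seed(1)
  t1 <- feature_table(matrix(rnorm(30 * 2048), 30), lab,
                      feature_ids = sprintf("ResNet-50:%04d", 1:2048))
  t2 <- feature_table(matrix(rnorm(30 * 1536), 30), lab,
                      feature_ids = sprintf("Inception-ResNet-v2:%04d", 1:1536))
  s1 <- network_run_summary("ResNet-50", "eo", 94.7, t1$feature_ids[1:562])
  s2 <- network_run_summary("Inception-ResNet-v2", "eo", 94.2, t2$feature_ids[1:376])
  cc <- concatenate_selected(list(`ResNet-50` = t1, `Inception-ResNet-v2` = t2),
                             list(s1, s2))
  expect_equal(ncol(cc$matrix), 938L)
  expect_identical(cc$contributing_networks, c("ResNet-50", "Inception-ResNet-v2"))
  expect_identical(as.character(cc$labels), lab)
  expect_equal(cc$matrix[, 1], t1$matrix[, 1])
  expect_equal(cc$matrix[, 563], t2$matrix[, 1])
  # single network passes through unchanged
  one <- concatenate_selected(list(`ResNet-50` = t1), list(s1))
  expect_equal(one$matrix, t1$matrix[, 1:562])
})

test_that("concatenation rejects mismatched samples and empty selections", {
  lab <- rep(c("a", "b"), each = 5)
  t1 <- feature_table(matrix(rnorm(10 * 3), 10), lab,
                      feature_ids = sprintf("A:%d", 1:3))
  t2 <- feature_table(matrix(rnorm(8 * 3), 8), rep(c("a", "b"), each = 4),
                      feature_ids = sprintf("B:%d", 1:3))
  s1 <- network_run_summary("A", "eo", 95, t1$feature_ids)
  s2 <- network_run_summary("B", "eo", 95, t2$feature_ids)
  expect_error(concatenate_selected(list(A = t1, B = t2), list(s1, s2)),
               "mismatch")
  expect_error(concatenate_selected(list(A = t1), list()),
               "no network passed threshold")
})

test_that("concatenating complementary networks recovers the union accuracy", {
  # two "networks" each carrying half of the informative columns
  syn <- make_synthetic_features(synthetic_spec(
    n_per_class = c(25L, 25L, 25L), d_total = 40L, k_informative = 8L,
    separation = 1.2, seed = 13))
  info <- which(syn$truth_mask == 1L)
  lab <- syn$table$labels
  half1 <- c(info[1:4], which(syn$truth_mask == 0L)[1:16])
  half2 <- c(info[5:8], which(syn$truth_mask == 0L)[17:32])
  t1 <- feature_table(syn$table$matrix[, half1], lab,
                      feature_ids = sprintf("NetA:%04d", seq_along(half1)))
  t2 <- feature_table(syn$table$matrix[, half2], lab,
                      feature_ids = sprintf("NetB:%04d", seq_along(half2)))
  sp <- stratified_holdout(lab, 0.2, seed = 13)
  a1 <- evaluate_mask(t1, sp, rep(1L, 20))$accuracy
  a2 <- evaluate_mask(t2, sp, rep(1L, 20))$accuracy
  s1 <- network_run_summary("NetA", "eo", 95, t1$feature_ids)
  s2 <- network_run_summary("NetB", "eo", 95, t2$feature_ids)
  cc <- concatenate_selected(list(NetA = t1, NetB = t2), list(s1, s2))
  out <- final_classifier(cc, sp)
  expect_gte(out$fitness$accuracy, max(a1, a2))
})

test_that("an optional second optimization pass runs on the concatenated set", {
  fx <- make_fixture(n = c(15L, 15L), d = 12L, k = 4L, seed = 14)
  s <- network_run_summary("NetA", "eo", 95, fx$table$feature_ids)
  cc <- concatenate_selected(list(NetA = fx$table), list(s))
  out <- final_classifier(cc, fx$split,
                          rerun = optimizer_config("eo", max_iterations = 8,
                                                   seed = 2))
  expect_s3_class(out$selection, "selection_result")
  expect_lte(out$selection$n_selected, ncol(cc$matrix))
})
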