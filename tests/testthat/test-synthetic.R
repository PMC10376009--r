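test_that("generation is fully determined by spec and seed", {
  spec <- synthetic_spec(n_per_class = c(10L, 10L, 10L), d_total = 20L,
                         k_informative = 5L, seed = 17)
  o1 <- make_synthetic_features(spec)
  o2 <- make_synthetic_features(spec)
  expect_identical(o1$table$matrix, o2$table$matrix)
  expect_identical(o1$truth_mask, o2$truth_mask)
  expect_equal(sum(o1$truth_mask), 5L)
  o3 <- make_synthetic_features(synthetic_spec(n_per_class = c(10L, 10L, 10L),
                                               d_total = 20L, k_informative = 5L,
                                               seed = 18))
  expect_false(identical(o1$table$matrix, o3$table$matrix))
})

test_that("separated classes are learnable and unseparated ones are not", {
  strong <- make_synthetic_features(synthetic_spec(seed = 19))
  sp <- stratified_holdout(strong$table$labels, 0.2, seed = 19)
  acc <- evaluate_mask(strong$table, sp, rep(1L, 200))$accuracy
  expect_gt(acc, 0.9)

  flat <- make_synthetic_features(synthetic_spec(separation = 0, seed = 19))
  acc0 <- evaluate_mask(flat$table, sp, rep(1L, 200))$accuracy
  # chance level is 1/3; allow generous binomial noise on 30 test samples
  expect_lt(abs(acc0 - 1 / 3), 0.25)
})

test_that("the planted mask beats disjoint random masks of equal size", {
  syn <- make_synthetic_features(synthetic_spec(
    n_per_class = c(30L, 30L, 30L), d_total = 60L, k_informative = 8L,
    separation = 1.5, seed = 20))
  sp <- stratified_holdout(syn$table$labels, 0.2, seed = 20)
  truth_acc <- evaluate_mask(syn$table, sp, syn$truth_mask)$accuracy
  noise_cols <- which(syn$truth_mask == 0L)
  set.seed(20)
  rand_accs <- replicate(20, {
    m <- integer(60)
    m[sample(noise_cols, 8)] <- 1L
    evaluate_mask(syn$table, sp, m)$accuracy
  })
  expect_true(all(truth_acc > rand_accs))
})

test_that("toy lesion images form a decodable byte-stable dataset", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  make_synthetic_images(c(benign = 4L, malignant = 2L, normal = 1L),
                        out_dir = d1, seed = 21)
  make_synthetic_images(c(benign = 4L, malignant = 2L, normal = 1L),
                        out_dir = d2, seed = 21)
  files1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
  expect_length(files1, 7L)
  files2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
  for (i in seq_along(files1)) {
    expect_identical(readBin(files1[i], "raw", file.size(files1[i])),
                     readBin(files2[i], "raw", file.size(files2[i])))
  }
  ds <- load_image_dataset(d1)
  expect_equal(nrow(ds$items), 7L)
})

test_that("mock features of the three lesion classes are distinguishable", {
  dir <- withr::local_tempdir()
  make_synthetic_images(c(benign = 8L, malignant = 8L, normal = 8L),
                        out_dir = dir, seed = 22)
  tab <- extract_features(load_image_dataset(dir), backbone_spec("ResNet-18"),
                          extraction_backend("mock", seed = 1))
  # per-image feature means differ across classes beyond 3 standard errors
  img_means <- rowMeans(tab$matrix)
  grp <- split(img_means, tab$labels)
  for (pair in combn(names(grp), 2, simplify = FALSE)) {
    a <- grp[[pair[1]]]; b <- grp[[pair[2]]]
    se <- sqrt(var(a) / length(a) + var(b) / length(b))
    expect_gt(abs(mean(a) - mean(b)) / se, 3)
  }
})

test_that("benchmark objectives match their closed forms", {
  sphere <- benchmark_function("sphere")
  expect_equal(sphere(rep(0, 10)), 0)
  expect_equal(sphere(rep(1, 10)), 10)
  ras <- benchmark_function("rastrigin-shifted")
  expect_equal(ras(rep(0.25, 10)), 0)
  expect_gt(ras(rep(0.9, 10)), 0)
  expect_error(benchmark_function("ackley"), "unknown benchmark")
})
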