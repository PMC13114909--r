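test_that("instance normalization z-scores each channel with floored variance", {
  v <- matrix(rnorm(10 * 120, mean = 5, sd = 3), 10, 120)
  v[3, ] <- 5  # constant channel
  m <- enose_measurement(v, "s1", 0L)
  mn <- instance_normalize(m)
  expect_equal(rowMeans(mn$values), rep(0, 10), tolerance = 1e-6)
  # population sd of every non-degenerate channel is 1
  sds <- sqrt(rowMeans(mn$values^2))
  expect_equal(sds[-3], rep(1, 9), tolerance = 1e-6)
  # constant channel maps to all zeros
  expect_equal(mn$values[3, ], rep(0, 120))
  # metadata untouched
  expect_identical(mn$sample_id, "s1")
  expect_identical(mn$day, 1L)
})

test_that("instance normalization matches the arithmetic-sequence oracle", {
  # channel holding t = 1..120: z(t) = (t - 60.5) / population sd
  v <- matrix(rep(1:120, each = 10), 10, 120)
  mn <- instance_normalize(enose_measurement(v, "s", 0L))
  mu <- mean(1:120)
  sigma <- sqrt(mean((1:120 - mu)^2))
  expect_equal(mn$values[1, ], (1:120 - mu) / sigma, tolerance = 1e-9)
  expect_equal(mn$values[5, 120], 1.71771, tolerance = 1e-4)
})

test_that("instance normalization is idempotent and rejects bad input", {
  ds <- tiny_dataset(2L, 2L, 2L)
  once <- instance_normalize(ds)
  twice <- instance_normalize(once)
  expect_equal(twice$x, once$x, tolerance = 1e-6)
  bad <- matrix(1, 10, 120)
  bad[1, 1] <- NA
  expect_error(instance_normalize(bad), "non-finite")
})

test_that("day-wise split partitions by day and reproduces the full-scale counts", {
  # 6 classes x 6/day x 10 days, train days 1-8, test days 9-10
  t1 <- generate_domain(sim_preset_target1(3), domain = "target")
  sp <- day_wise_split(t1, split_spec(1:8, 9:10))
  expect_equal(length(sp$train), 288L)
  expect_equal(length(sp$test), 72L)
  expect_length(intersect(sp$train$sample_id, sp$test$sample_id), 0L)
  expect_true(all(sp$train$day <= 8))
  expect_true(all(sp$test$day >= 9))
  expect_equal(unname(sp$report$train_counts), rep(48L, 6))
  expect_equal(unname(sp$report$test_counts), rep(12L, 6))

  # 8 classes x 6/day x 10 days
  t2 <- generate_domain(sim_preset_target2(3), domain = "target")
  sp2 <- day_wise_split(t2, split_spec(1:8, 9:10))
  expect_equal(length(sp2$train), 384L)
  expect_equal(length(sp2$test), 96L)
})

test_that("day-wise split flags empty test sets and unknown days", {
  ds <- tiny_dataset(2L, 1L, 3L)
  sp <- day_wise_split(ds, split_spec(1:3, integer(0)))
  expect_null(sp$test)
  expect_true(sp$report$empty_test)
  expect_equal(length(sp$train), length(ds))
  expect_error(day_wise_split(ds, split_spec(1:2, 4L)), "day")
})

test_that("stratified validation split allocates by largest remainder", {
  t1 <- generate_domain(sim_preset_target1(5), domain = "target")
  train <- day_wise_split(t1, split_spec(1:8, 9:10))$train  # 288, 48/class
  sp <- stratified_validation_split(train, 0.2, seed = 9L)
  expect_equal(length(sp$val), 58L)
  expect_equal(length(sp$fit), 230L)
  expect_true(all(class_counts(sp$val) %in% c(9L, 10L)))
  # disjoint union
  expect_setequal(c(sp$fit$sample_id, sp$val$sample_id), train$sample_id)
  # determinism
  sp2 <- stratified_validation_split(train, 0.2, seed = 9L)
  expect_identical(sp$val$sample_id, sp2$val$sample_id)
  # forced one-per-class case
  small <- tiny_dataset(3L, 1L, 2L)  # 2 per class
  half <- stratified_validation_split(small, 0.5, seed = 1L)
  expect_equal(unname(class_counts(half$val)), rep(1L, 3))
  # errors
  expect_error(stratified_validation_split(train, 0, 1L), "frac")
  expect_error(stratified_validation_split(train, 1, 1L), "frac")
  one <- tiny_dataset(2L, 1L, 1L)   # 1 per class
  expect_error(stratified_validation_split(one, 0.5, 1L), ">= 2")
})

test_that("stratified subsampling reproduces the label-efficiency counts", {
  # round-half-up totals for both target sizes at every protocol ratio
  expect_identical(
    vapply(c(0.8, 0.6, 0.4, 0.2), function(r) subsample_total(288L, r), 0L),
    c(230L, 173L, 115L, 58L)
  )
  expect_identical(
    vapply(c(0.8, 0.6, 0.4, 0.2), function(r) subsample_total(384L, r), 0L),
    c(307L, 230L, 154L, 77L)
  )
  t1 <- generate_domain(sim_preset_target1(7), domain = "target")
  train <- day_wise_split(t1, split_spec(1:8, 9:10))$train
  sub <- stratified_subsample(train, 0.8, seed = 3L)
  expect_equal(length(sub), 230L)
  expect_true(max(class_counts(sub)) - min(class_counts(sub)) <= 1L)
  # identity at ratio 1 and determinism
  expect_identical(stratified_subsample(train, 1, 5L)$sample_id,
                   train$sample_id)
  expect_identical(stratified_subsample(train, 0.4, 8L)$sample_id,
                   stratified_subsample(train, 0.4, 8L)$sample_id)
  expect_error(stratified_subsample(train, 0, 1L), "ratio")
  expect_error(stratified_subsample(train, 1.2, 1L), "ratio")
})

test_that("standardizer fits on training statistics only", {
  s <- fit_standardizer(matrix(c(0, 2), 2, 1))
  expect_equal(unname(s$mean), 1)
  expect_equal(unname(s$std), 1)
  expect_equal(apply_standardizer(s, matrix(4, 1, 1))[1, 1], 3)
  # applying to the fitting set gives exact z-scores
  X <- matrix(rnorm(60), 20, 3)
  X[, 2] <- 7  # constant column
  s2 <- fit_standardizer(X)
  Z <- apply_standardizer(s2, X)
  expect_equal(colMeans(Z), rep(0, 3), tolerance = 1e-6)
  expect_equal(sqrt(colMeans(Z^2))[-2], rep(1, 2), tolerance = 1e-6)
  expect_equal(Z[, 2], rep(0, 20))
  expect_error(apply_standardizer(s2, matrix(0, 1, 2)), "mismatch")
})

test_that("CSV round trip preserves data and metadata", {
  ds <- tiny_dataset(2L, 1L, 2L, seed = 13L, domain = "target")
  path <- tempfile(fileext = ".csv")
  write_enose_csv(ds, path)
  back <- read_enose_csv(path, n_classes = ds$n_classes)
  ord <- match(ds$sample_id, back$sample_id)
  expect_equal(back$x[ord, , ], ds$x, tolerance = 1e-12)
  expect_identical(back$class_label[ord], ds$class_label)
  expect_identical(back$day[ord], ds$day)
  unlink(path)
})

test_that("split manifests record partitions for leakage audits", {
  spec <- split_spec(1:8, 9:10, seed = 4L)
  path <- tempfile(fileext = ".json")
  write_split_manifest(path, spec, train = c("a", "b"), test = c("c"))
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(man$partitions$train, c("a", "b"))
  expect_equal(man$spec$test_days, 9:10)
  unlink(path)
})
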