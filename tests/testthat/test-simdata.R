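test_that("noiseless measurements follow the closed-form kinetic law", {
  cfg <- noiseless_config(A = 2, tau = 20, B = 1)
  m <- simulate_measurement(cfg, domain_shift(), class_k = 0L, day = 1L)
  # value at 0-based t = 20 is B + A (1 - exp(-1))
  expect_equal(m$values[1, 21], 1 + 2 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(m$values[1, 21], 2.26424, tolerance = 1e-5)
  # t = 0 is exactly the baseline
  expect_equal(m$values[, 1], rep(1, 10))
  expect_equal(dim(m$values), c(10L, 120L))
  # full-curve oracle equivalence on every channel
  t <- 0:119
  expect_equal(m$values, matrix(1 + 2 * (1 - exp(-t / 20)), 10, 120,
                                byrow = TRUE), tolerance = 1e-12)
})

test_that("noiseless zero-drift responses are non-decreasing in time", {
  cfg <- noiseless_config(n_classes = 3L)
  cfg$class_patterns <- matrix(runif(30, 0, 3), 3, 10)
  for (k in 0:2) {
    m <- simulate_measurement(cfg, domain_shift(), class_k = k, day = 1L)
    expect_true(all(diff(t(m$values)) >= -1e-12))
  }
})

test_that("simulate_measurement validates class and day", {
  cfg <- noiseless_config()
  expect_error(simulate_measurement(cfg, domain_shift(), class_k = 5L, day = 1L),
               "class_k")
  expect_error(simulate_measurement(cfg, domain_shift(), class_k = 0L, day = 9L),
               "day")
})

test_that("generate_domain produces balanced, deterministic campaigns", {
  src <- generate_domain(sim_preset_source(21))
  expect_equal(length(src), 1440L)
  expect_equal(unname(class_counts(src)), rep(120L, 12))
  t1 <- generate_domain(sim_preset_target1(21), domain = "target")
  expect_equal(length(t1), 360L)
  t2 <- generate_domain(sim_preset_target2(21), domain = "target")
  expect_equal(length(t2), 480L)
  # balanced per class per day
  tab <- table(t1$class_label, t1$day)
  expect_true(all(tab == 6L))
  # bit-identical regeneration from the same seed
  src2 <- generate_domain(sim_preset_source(21))
  expect_identical(src$x, src2$x)
  expect_identical(src$sample_id, src2$sample_id)
})

test_that("steady-state class-pattern recovery from zero-noise samples", {
  cfg <- sim_config(
    n_classes = 2L, samples_per_class_per_day = 5L, n_days = 2L,
    class_patterns = matrix(c(1, 2), 2, 10),
    class_tau_mult = matrix(1, 2, 10),
    class_transient = matrix(0, 2, 10),
    tau = rep(15, 10), noise_sd = 0, day_gain_sd = 0, drift_slope_sd = 0,
    seed = 3L
  )
  ds <- generate_domain(cfg)
  feats <- steady_state_features(ds)
  # exact closed-form mean of the rise curve over the last 20 steps
  window <- 100:119
  for (k in 0:1) {
    A <- cfg$class_patterns[k + 1L, 1L]
    expected <- 1 + A * (1 - mean(exp(-window / 15)))
    got <- colMeans(feats[ds$class_label == k, , drop = FALSE])
    expect_equal(unname(got), rep(expected, 10), tolerance = 1e-9)
    # and B + A up to the exponential tail the window retains
    expect_equal(unname(got), rep(1 + A, 10),
                 tolerance = A * exp(-100 / 15) * 1.1 + 1e-9)
  }
})

test_that("domain shift identity detection and benchmark structure", {
  expect_true(is_identity_shift(domain_shift()))
  expect_false(is_identity_shift(domain_shift(tau_scale = 1.2)))
  bench <- make_transfer_benchmark(seed = 5, difficulty = 0,
                                   source_samples_per_day = 1L,
                                   source_days = 2L,
                                   target_samples_per_day = 1L,
                                   target_days = 2L)
  expect_true(is_identity_shift(bench$shift))
  expect_equal(bench$source$n_classes, 12L)
  expect_equal(bench$target$n_classes, 6L)
  # same seed -> bit-identical benchmark
  bench2 <- make_transfer_benchmark(seed = 5, difficulty = 0,
                                    source_samples_per_day = 1L,
                                    source_days = 2L,
                                    target_samples_per_day = 1L,
                                    target_days = 2L)
  expect_identical(bench$target$x, bench2$target$x)
})

test_that("steady-state domain discrepancy grows with benchmark difficulty", {
  # the shift magnitude dial must actually move the source-target
  # discrepancy in raw steady-state feature space
  mmd_at <- function(difficulty, s) {
    bench <- make_transfer_benchmark(seed = s, difficulty = difficulty,
                                     source_samples_per_day = 2L,
                                     source_days = 3L,
                                     target_samples_per_day = 2L,
                                     target_days = 3L)
    multikernel_mmd(steady_state_features(bench$source),
                    steady_state_features(bench$target))$combined
  }
  for (s in 1:3) {
    m0 <- mmd_at(0, s)
    m5 <- mmd_at(0.5, s)
    m10 <- mmd_at(1, s)
    expect_lt(m0, m5)
    expect_lt(m0, m10)
  }
})

test_that("target classes overlap in 2-PC steady-state space", {
  # the target tasks are not linearly trivial: first-two-component
  # silhouettes stay clearly below perfect separation across seeds
  for (s in 1:3) {
    bench <- make_transfer_benchmark(seed = s, difficulty = 0.5,
                                     source_samples_per_day = 2L,
                                     source_days = 3L,
                                     target_samples_per_day = 2L,
                                     target_days = 3L)
    p <- pca_summary(steady_state_features(bench$target))
    sil <- cluster::silhouette(bench$target$class_label + 1L,
                               dist(p$scores[, 1:2]))
    expect_lt(mean(sil[, 3]), 0.95)
  }
})
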