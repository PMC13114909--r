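test_that("label smoothing produces the stated targets and losses", {
  # smoothed targets at eps = 0.05, C = 6
  eps <- 0.05
  C <- 6L
  expect_equal((1 - eps) + eps / C, 0.958333, tolerance = 1e-6)
  expect_equal(eps / C, 0.008333, tolerance = 1e-4)
  # uniform logits: loss = ln C for any eps since targets sum to 1
  logits <- matrix(0, 4, C)
  y <- c(0L, 2L, 4L, 5L)
  expect_equal(smoothed_cross_entropy(logits, y, eps), log(6), tolerance = 1e-12)
  expect_equal(smoothed_cross_entropy(logits, y, 0.3), log(6), tolerance = 1e-12)
  # eps = 0 reduces to the standard cross-entropy
  set.seed(1)
  logits <- matrix(rnorm(4 * C), 4, C)
  p <- exp(logits) / rowSums(exp(logits))
  manual <- -mean(log(p[cbind(1:4, y + 1L)]))
  expect_equal(smoothed_cross_entropy(logits, y, 0), manual, tolerance = 1e-10)
})

test_that("smoothed cross-entropy is bounded below by the target entropy", {
  set.seed(2)
  eps <- 0.05
  C <- 5L
  # entropy of the smoothed target for a one-hot base label
  yt <- rep(eps / C, C)
  yt[1] <- yt[1] + 1 - eps
  target_entropy <- -sum(yt * log(yt))
  for (i in 1:50) {
    logits <- matrix(rnorm(3 * C, sd = 3), 3, C)
    y <- sample(0:(C - 1L), 3, replace = TRUE)
    expect_gte(smoothed_cross_entropy(logits, y, eps), target_entropy - 1e-10)
  }
})

test_that("center loss follows its closed forms", {
  centers <- matrix(rnorm(3 * 128), 3, 128)
  # all features at their centers
  h <- centers[c(1, 2, 3, 1) , ]
  expect_equal(center_loss(h, c(0L, 1L, 2L, 0L), centers), 0)
  # two samples at c +- u: loss = ||u||^2
  u <- rnorm(128)
  h2 <- rbind(centers[1, ] + u, centers[1, ] - u)
  expect_equal(center_loss(h2, c(0L, 0L), centers), sum(u^2), tolerance = 1e-9)
  # single sample at distance (3, 4, 0, ...): loss 25
  h3 <- centers[2, , drop = FALSE]
  h3[1, 1:2] <- h3[1, 1:2] + c(3, 4)
  expect_equal(center_loss(h3, 1L, centers), 25)
  expect_error(center_loss(h3, 5L, centers), "center")
})

test_that("center updates follow one plain SGD step with lr 0.5", {
  centers <- matrix(rnorm(3 * 128), 3, 128)
  # batch sitting exactly on the centers: no movement
  h <- centers[c(1, 2), ]
  expect_identical(update_centers(h, c(0L, 1L), centers, 0.5), centers)
  # single sample: c' = c + 2 * 0.5 * (h - c) = h
  h1 <- matrix(rnorm(128), 1, 128)
  upd <- update_centers(h1, 0L, centers, 0.5)
  expect_equal(upd[1, ], h1[1, ], tolerance = 1e-12)
  # absent classes are bit-identical
  expect_identical(upd[2:3, ], centers[2:3, ])
})

test_that("domain adversarial loss matches the double-sum oracle", {
  cfg <- mgda_config(4)
  params <- init_mgda_params(cfg, 3)$params
  set.seed(11)
  fs <- matrix(rnorm(3 * 128), 3, 128)
  ft <- matrix(rnorm(2 * 128), 2, 128)
  adv <- domain_adversarial_loss(fs, ft, params, cfg, "local",
                                 lambda = 0.1, training = FALSE)
  # independent oracle: explicit probabilities and the printed double sum
  D <- 1 / (1 + exp(-adv$logits))
  n_s <- 3L
  manual <- -(sum(log(1 - D[1:n_s])) + sum(log(D[-(1:n_s)]))) / 5
  expect_equal(adv$loss, manual, tolerance = 1e-9)
  # chance-level discriminator (zero weights -> logit 0) gives ln 2
  zero <- params
  for (nm in grep("^dloc", names(zero), value = TRUE)) {
    zero[[nm]] <- zero[[nm]] * 0
  }
  adv0 <- domain_adversarial_loss(fs, ft, zero, cfg, "local", 0.1, FALSE)
  expect_equal(adv0$loss, log(2), tolerance = 1e-12)
  expect_error(
    domain_adversarial_loss(NULL, ft, params, cfg, "local", 0.1, FALSE),
    "both domains"
  )
})

test_that("gradient reversal scales and zeroes the feature-side gradient", {
  # forward is the identity
  f <- c(1, -2, 3)
  expect_identical(grl_apply(f, 0.2), f)
  # downstream loss = sum(outputs): gradient is all ones, reversed by -lambda
  expect_equal(grl_backward(rep(1, 3), 0.2), rep(-0.2, 3))
  expect_equal(grl_backward(rep(1, 3), 0), rep(0, 3))
  # through a real discriminator: reversed gradient equals -lambda times the
  # finite-difference gradient of the adversarial loss
  cfg <- mgda_config(4)
  params <- init_mgda_params(cfg, 5)$params
  set.seed(21)
  fs <- matrix(rnorm(2 * 128), 2, 128)
  ft <- matrix(rnorm(2 * 128), 2, 128)
  lam <- 0.2
  adv <- domain_adversarial_loss(fs, ft, params, cfg, "local", lam, FALSE)
  back <- mgdanet:::domain_adversarial_bwd(adv)
  eps <- 1e-5
  for (j in c(1L, 50L, 128L)) {
    up <- fs; up[1, j] <- up[1, j] + eps
    dn <- fs; dn[1, j] <- dn[1, j] - eps
    fd <- (domain_adversarial_loss(up, ft, params, cfg, "local", lam, FALSE)$loss -
           domain_adversarial_loss(dn, ft, params, cfg, "local", lam, FALSE)$loss) /
      (2 * eps)
    expect_equal(back$df_features[1, j], -lam * fd, tolerance = 1e-4)
  }
})

test_that("the reversal-intensity schedule is sigmoidal, bounded, monotone", {
  expect_equal(lambda_schedule(0, 100, 0.2), 0)
  expect_equal(lambda_schedule(100, 100, 0.2),
               0.2 * (2 / (1 + exp(-10)) - 1), tolerance = 1e-12)
  expect_equal(lambda_schedule(100, 100, 0.2), 0.199982, tolerance = 1e-6)
  expect_equal(lambda_schedule(50, 100, 0.1),
               0.1 * (2 / (1 + exp(-5)) - 1), tolerance = 1e-12)
  expect_equal(lambda_schedule(50, 100, 0.1), 0.098661, tolerance = 1e-5)
  grid <- vapply(0:200, function(e) lambda_schedule(e, 200, 0.2), 0)
  expect_true(all(diff(grid) > 0))
  expect_true(all(grid >= 0 & grid < 0.2))
  expect_error(lambda_schedule(1, 0, 0.2), "E")
})

test_that("stage losses are the stated weighted sums", {
  expect_equal(stage1_loss(1, 2, 0.01), 1.02)
  expect_equal(stage1_loss(1.5, 7, 0), 1.5)
  expect_equal(stage2_loss(1, log(2), log(2), 0.5), 1 + log(2),
               tolerance = 1e-12)
  expect_equal(1 + 0.5 * 2 * log(2), 1.693147, tolerance = 1e-6)
})
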