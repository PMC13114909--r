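# Reduced-scale training behavior: learnability on separable data,
# reproducibility, leakage guards, and stage bookkeeping. Sizes are kept
# small so the whole file runs in about a minute.

make_easy_source <- function(seed = 51L, n_classes = 4L) {
  # well-separated kinetic signatures, low noise
  cfg <- sim_config(
    n_classes = n_classes, samples_per_class_per_day = 4L, n_days = 3L,
    class_tau_mult = matrix(exp(seq(-0.8, 0.8, length.out = n_classes)),
                            n_classes, 10),
    noise_sd = 0.005, day_gain_sd = 0.02, drift_slope_sd = 0, seed = seed
  )
  generate_domain(cfg)
}

test_that("source pretraining learns a separable synthetic source", {
  src <- make_easy_source()
  cfg <- mgda_config(4)
  init <- init_mgda_params(cfg, 1)
  ck <- pretrain_source(src, cfg, init$params, init$bn, epochs = 10L,
                        seed = 1L)
  expect_gte(ck$best_val_acc, 0.8)
  expect_equal(ck$stage, "pretrain")
  expect_true(ck$best_epoch >= 0 && ck$best_epoch < 10)
  # fit/val manifests are disjoint and cover the source
  expect_length(intersect(ck$fit_ids, ck$val_ids), 0L)
  expect_setequal(c(ck$fit_ids, ck$val_ids), src$sample_id)
})

test_that("training is bit-reproducible for a fixed seed", {
  src <- make_easy_source(seed = 52L)
  cfg <- mgda_config(4)
  init <- init_mgda_params(cfg, 2)
  ck_a <- pretrain_source(src, cfg, init$params, init$bn, epochs = 2L,
                          seed = 7L)
  ck_b <- pretrain_source(src, cfg, init$params, init$bn, epochs = 2L,
                          seed = 7L)
  expect_identical(ck_a$params, ck_b$params)
  expect_identical(ck_a$history$val_acc, ck_b$history$val_acc)
  ck_c <- pretrain_source(src, cfg, init$params, init$bn, epochs = 2L,
                          seed = 8L)
  expect_false(identical(ck_a$params, ck_c$params))
})

test_that("adversarial alignment ignores target labels and schedules lambda", {
  src <- make_easy_source(seed = 53L)
  tgt <- tiny_dataset(4L, 2L, 3L, seed = 54L, domain = "target")
  cfg <- mgda_config(4)
  init <- init_mgda_params(cfg, 3)
  ck1 <- pretrain_source(src, cfg, init$params, init$bn, epochs = 2L,
                         seed = 1L)
  # scrambling target labels must not change Stage 2 at all
  tgt_scrambled <- tgt
  tgt_scrambled$class_label <- rev(tgt$class_label)
  ck2a <- adversarial_align(ck1, src, tgt, cfg, epochs = 2L, seed = 4L)
  ck2b <- adversarial_align(ck1, src, tgt_scrambled, cfg, epochs = 2L,
                            seed = 4L)
  expect_identical(ck2a$params, ck2b$params)
  # reversal intensity starts at zero and grows
  expect_equal(ck2a$history$lambda_local[1], 0)
  expect_equal(ck2a$history$lambda_global[1], 0)
  expect_gt(ck2a$history$lambda_local[2], 0)
  expect_lte(max(ck2a$history$lambda_local), 0.2)
  expect_lte(max(ck2a$history$lambda_global), 0.1)
  expect_error(adversarial_align(ck1, src, tgt[integer(0)], cfg), "empty")
})

test_that("stage 2 keeps gradient flow to the classifier head", {
  src <- make_easy_source(seed = 55L)
  tgt <- tiny_dataset(4L, 2L, 3L, seed = 56L, domain = "target")
  cfg <- mgda_config(4)
  init <- init_mgda_params(cfg, 5)
  ck1 <- pretrain_source(src, cfg, init$params, init$bn, epochs = 1L,
                         seed = 1L)
  ck2 <- adversarial_align(ck1, src, tgt, cfg, epochs = 1L, seed = 1L)
  # the source classification term updates the classifier parameters
  expect_false(identical(ck2$params$cls2_W, ck1$params$cls2_W))
})

test_that("fine-tuning swaps the head and respects label spaces", {
  src <- make_easy_source(seed = 57L)
  cfg <- mgda_config(4)
  init <- init_mgda_params(cfg, 6)
  ck1 <- pretrain_source(src, cfg, init$params, init$bn, epochs = 1L,
                         seed = 1L)
  tgt <- tiny_dataset(3L, 2L, 5L, seed = 58L, domain = "target")
  ck3 <- finetune_target(ck1, tgt, 3L, cfg, epochs = 2L, seed = 2L)
  expect_equal(ck3$cfg$n_classes, 3L)
  expect_equal(dim(ck3$centers), c(3L, 128L))
  expect_equal(ncol(ck3$params$cls2_W), 3L)
  expect_error(finetune_target(ck1, tgt, 5L, cfg, epochs = 1L, seed = 1L),
               "match")
})

test_that("the fitted model object predicts, evaluates, and guards leakage", {
  src <- make_easy_source(seed = 59L)
  tgt <- tiny_dataset(3L, 2L, 5L, seed = 60L, domain = "target",
                      noise_sd = 0.005)
  sp <- day_wise_split(tgt, split_spec(1:4, 5L))
  fit <- mgda_net(src, sp$train, target_test = sp$test,
                  epochs = c(pretrain = 4L, align = 2L, finetune = 6L),
                  seed = 3L)
  expect_s3_class(fit, "mgda_net")
  expect_s3_class(fit$test_metrics, "metrics_report")
  # no stage saw the held-out day
  seen <- c(fit$checkpoints$stage1$fit_ids, fit$checkpoints$stage1$val_ids)
  expect_length(intersect(seen, sp$test$sample_id), 0L)
  # evaluation is deterministic and repeatable
  m1 <- evaluate_model(fit, sp$test)
  m2 <- evaluate_model(fit, sp$test)
  expect_identical(m1$confusion, m2$confusion)
  expect_identical(m1$overall_accuracy, fit$test_metrics$overall_accuracy)
  # all five metrics plus the confusion matrix are reported
  expect_named(
    m1,
    c("confusion", "overall_accuracy", "per_class_precision",
      "per_class_recall", "precision_macro", "recall_macro", "f1_macro",
      "kappa", "observed_agreement", "expected_agreement", "n_samples",
      "n_classes"),
    ignore.order = TRUE
  )
  # label-space mismatch is refused
  wrong <- tiny_dataset(5L, 1L, 2L, seed = 61L, domain = "target")
  expect_error(evaluate_model(fit, wrong), "mismatch")
  # predictions have the right range and length
  pred <- predict(fit, sp$test)
  expect_length(pred, length(sp$test))
  expect_true(all(pred >= 0 & pred < 3))
  probs <- predict(fit, sp$test, type = "prob")
  expect_equal(rowSums(probs), rep(1, length(sp$test)), tolerance = 1e-9)
  # feature taps carry the contracted widths
  expect_equal(ncol(extract_level_features(fit, sp$test, "local")), 128L)
  expect_equal(ncol(extract_level_features(fit, sp$test, "global")), 128L)
  expect_equal(ncol(extract_level_features(fit, sp$test, "fused")), 256L)
})

test_that("ablation variants change exactly the advertised component", {
  # parameter-count and architecture assertions, no training required
  n_par <- function(variant) {
    vc <- mgdanet:::variant_config(variant, 8L)
    init <- init_mgda_params(vc$cfg, 1)
    nms <- names(init$params)
    nms <- nms[!startsWith(nms, "dloc") & !startsWith(nms, "dglob")]
    sum(vapply(init$params[nms], length, 0L))
  }
  expect_lt(n_par("cnn_only"), n_par("full"))
  expect_lt(n_par("attn_only"), n_par("full"))
  expect_lt(n_par("concat_fusion"), n_par("full"))  # no gate weights
  expect_equal(n_par("no_da"), n_par("full"))       # same architecture
  vc <- mgdanet:::variant_config("local_only_da", 8L)
  expect_true(vc$use_local && !vc$use_global)
  vc <- mgdanet:::variant_config("global_only_da", 8L)
  expect_true(!vc$use_local && vc$use_global)
  vc <- mgdanet:::variant_config("no_finetune", 8L)
  expect_false(vc$do_finetune)
  expect_true(vc$do_align)
  expect_error(mgdanet:::variant_config("bogus", 8L))
  expect_length(mgdanet:::ALL_VARIANTS, 8L)
})
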