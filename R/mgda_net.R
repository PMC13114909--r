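#' Fit MGDA-Net: three-stage cross-domain E-nose classification
#'
#' The single entry point for the full transfer protocol. Stage 1 pretrains
#' the dual-branch network on the labeled source domain (smoothed
#' cross-entropy + center loss, best-validation checkpoint); Stage 2 aligns
#' source and target feature distributions with branch-level domain
#' discriminators behind gradient reversal (target labels unused); Stage 3
#' swaps in a classifier head sized to the target label space and fine-tunes
#' with differential learning rates. Ablation variants switch off exactly one
#' component.
#'
#' Dataset-level standardization statistics are fitted on the source training
#' set only and stored in the returned object so prediction applies the same
#' preprocessing.
#'
#' @param source labeled source-domain [enose_dataset()].
#' @param target_train labeled target-domain training [enose_dataset()]
#'   (labels are only read in Stage 3).
#' @param target_test optional held-out target test set; when supplied the
#'   fitted object carries a [metrics_report()] on it.
#' @param variant `"full"` or one of the ablations `"cnn_only"`,
#'   `"attn_only"`, `"concat_fusion"`, `"no_da"`, `"local_only_da"`,
#'   `"global_only_da"`, `"no_finetune"`.
#' @param epochs named integer vector `c(pretrain=, align=, finetune=)`
#'   (protocol defaults 200/200/300).
#' @param batch_size mini-batch size for every stage.
#' @param seed master seed; all stage/init/batching randomness derives from
#'   it.
#' @param val_fraction stratified validation fraction for Stages 1 and 3.
#' @param losses a [loss_config()].
#' @param verbose print per-stage progress.
#' @param finetune_train optional labeled dataset for Stage 3 only (defaults
#'   to `target_train`); label-efficiency experiments pass the subsampled
#'   labeled set here while Stage 2 still aligns on the full training
#'   portion.
#' @param .cache optional environment reusing Stage-1/2 checkpoints across
#'   variants that share them (same data, seed and settings) — used by
#'   [run_ablation()] and [run_label_efficiency()].
#' @return an object of class `mgda_net`.
#' @export
mgda_net <- function(source, target_train, target_test = NULL,
                     variant = c("full", "cnn_only", "attn_only",
                                 "concat_fusion", "no_da", "local_only_da",
                                 "global_only_da", "no_finetune"),
                     epochs = c(pretrain = 200L, align = 200L,
                                finetune = 300L),
                     batch_size = 32L, seed = 1L, val_fraction = 0.2,
                     losses = loss_config(), verbose = FALSE,
                     finetune_train = NULL, .cache = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(source, "enose_dataset"),
            inherits(target_train, "enose_dataset"))
  epochs <- check_epochs(epochs)
  vc <- variant_config(variant, source$n_classes)
  std <- fit_standardizer(flatten_dataset(source), "source_train")
  src_std <- standardize_dataset(source, std)
  tgt_std <- standardize_dataset(target_train, std)
  if (is.null(finetune_train)) finetune_train <- target_train
  ft_std <- standardize_dataset(finetune_train, std)
  init <- init_mgda_params(vc$cfg, seed)
  say <- function(...) if (verbose) message(...)

  cached <- function(key, thunk) {
    if (is.null(.cache)) return(thunk())
    if (!is.null(.cache[[key]])) return(.cache[[key]])
    .cache[[key]] <- thunk()
    .cache[[key]]
  }
  arch_key <- paste(seed, vc$cfg$use_cnn, vc$cfg$use_attn, vc$cfg$fusion,
                    epochs[["pretrain"]], sep = "|")
  say("Stage 1: source pretraining (", epochs[["pretrain"]], " epochs)")
  ck1 <- cached(paste0("s1|", arch_key), function() {
    pretrain_source(src_std, vc$cfg, init$params, init$bn,
                    epochs = epochs[["pretrain"]],
                    batch_size = batch_size,
                    val_fraction = val_fraction, losses = losses,
                    seed = seed)
  })
  ck2 <- NULL
  if (vc$do_align) {
    say("Stage 2: adversarial alignment (", epochs[["align"]], " epochs)")
    ck2 <- cached(
      paste0("s2|", arch_key, "|", vc$use_local, "|", vc$use_global, "|",
             epochs[["align"]]),
      function() {
        adversarial_align(ck1, src_std, tgt_std, vc$cfg,
                          epochs = epochs[["align"]],
                          batch_size = batch_size,
                          use_local = vc$use_local,
                          use_global = vc$use_global,
                          losses = losses, seed = seed)
      }
    )
  }
  base_ck <- if (is.null(ck2)) ck1 else ck2
  probe <- NULL
  if (vc$do_finetune) {
    say("Stage 3: target fine-tuning (", epochs[["finetune"]], " epochs)")
    s3_key <- paste0("s3|", arch_key, "|", variant, "|",
                     epochs[["finetune"]], "|",
                     id_fingerprint(finetune_train$sample_id))
    ck3 <- cached(s3_key, function() {
      finetune_target(base_ck, ft_std, finetune_train$n_classes, vc$cfg,
                      epochs = epochs[["finetune"]],
                      batch_size = batch_size,
                      val_fraction = val_fraction, losses = losses,
                      seed = seed)
    })
    final_params <- ck3$params
    final_bn <- ck3$bn
    final_cfg <- ck3$cfg
    centers <- ck3$centers
    history3 <- ck3$history
  } else {
    # frozen-feature linear probe: across heterogeneous label spaces the
    # source head cannot emit target classes, so the no-fine-tuning variant
    # is evaluated through a multinomial logistic probe trained on the
    # frozen fused features of the labeled target training set
    say("Stage 3 skipped: fitting linear probe on frozen features")
    feats <- network_features(base_ck$params, base_ck$bn, vc$cfg,
                              ft_std$x, "fused")
    probe <- fit_linear_probe(feats, finetune_train$class_label,
                              finetune_train$n_classes,
                              epochs = epochs[["finetune"]],
                              batch_size = batch_size,
                              label_smoothing = losses$label_smoothing,
                              val_fraction = val_fraction, seed = seed)
    ck3 <- NULL
    final_params <- base_ck$params
    final_bn <- base_ck$bn
    final_cfg <- vc$cfg
    centers <- base_ck$centers
    history3 <- NULL
  }
  fit <- structure(
    list(
      variant = variant,
      cfg = final_cfg,
      source_cfg = vc$cfg,
      params = final_params,
      bn = final_bn,
      centers = centers,
      standardizer = std,
      probe = probe,
      n_target_classes = target_train$n_classes,
      target_class_names = target_train$class_names,
      checkpoints = list(stage1 = strip_history(ck1),
                         stage2 = strip_history(ck2)),
      history = list(stage1 = ck1$history,
                     stage2 = if (is.null(ck2)) NULL else ck2$history,
                     stage3 = history3),
      epochs = epochs, batch_size = batch_size, seed = seed,
      losses = losses,
      call = match.call()
    ),
    class = "mgda_net"
  )
  if (!is.null(target_test)) {
    fit$test_metrics <- evaluate_model(fit, target_test)
  }
  fit
}

check_epochs <- function(epochs) {
  if (is.null(names(epochs))) {
    names(epochs) <- c("pretrain", "align", "finetune")[seq_along(epochs)]
  }
  need <- c("pretrain", "align", "finetune")
  if (!all(need %in% names(epochs))) stop("epochs needs pretrain/align/finetune")
  ep <- vapply(need, function(k) as.integer(epochs[[k]]), 0L)
  if (any(ep < 1L)) stop("epochs must all be >= 1")
  ep
}

variant_config <- function(variant, n_source_classes) {
  variant <- match.arg(variant, ALL_VARIANTS)
  use_cnn <- variant != "attn_only"
  use_attn <- variant != "cnn_only"
  fusion <- if (!use_cnn || !use_attn) {
    "single"
  } else if (variant == "concat_fusion") {
    "concat"
  } else {
    "gate"
  }
  list(
    cfg = mgda_config(n_source_classes, use_cnn = use_cnn,
                      use_attn = use_attn, fusion = fusion),
    do_align = variant != "no_da",
    do_finetune = variant != "no_finetune",
    use_local = use_cnn && !(variant == "global_only_da"),
    use_global = use_attn && !(variant == "local_only_da")
  )
}

# short deterministic fingerprint of a sample-id set (order-insensitive)
id_fingerprint <- function(ids) {
  ids <- sort(ids)
  h <- 5381
  for (b in utf8ToInt(paste(ids, collapse = "|"))) {
    h <- (h * 33 + b) %% 2147483647
  }
  paste0(length(ids), "-", h)
}

standardize_dataset <- function(ds, std) {
  unflatten_dataset(ds, apply_standardizer(std, flatten_dataset(ds)))
}

strip_history <- function(ck) {
  if (is.null(ck)) return(NULL)
  ck$history <- NULL
  ck
}

# Schedule-matched linear probe on frozen features: a single linear layer
# trained under the same regime as the Stage-3 classifier head (Adam at the
# new-head learning rate, cosine annealing, identical epoch budget, batch
# size, stratified 20% validation and best-validation checkpointing), so
# the no-fine-tuning ablation changes exactly one component — the absence
# of Stage 3 — and not also the optimization budget.
fit_linear_probe <- function(features, labels, n_classes, epochs,
                             batch_size = 32L, lr = 1e-4,
                             label_smoothing = 0.05, val_fraction = 0.2,
                             seed = 1L) {
  n <- nrow(features)
  d <- ncol(features)
  with_seed(derive_seed(seed, "probe"), {
    W <- glorot_mat(d, n_classes)
    b <- rep(0, n_classes)
    # stratified validation split over row indices
    val_idx <- integer(0)
    counts <- tabulate(labels + 1L, n_classes)
    n_val <- max(1L, round_half_up(val_fraction * n))
    alloc <- largest_remainder_alloc(counts, n_val, seed)
    for (k in seq_len(n_classes)) {
      members <- which(labels == k - 1L)
      if (alloc[k] > 0L && length(members) > 1L) {
        val_idx <- c(val_idx, sample(members, min(alloc[k],
                                                  length(members) - 1L)))
      }
    }
    fit_idx <- setdiff(seq_len(n), val_idx)
    m_W <- W * 0; v_W <- W * 0; m_b <- b; v_b <- b
    t_step <- 0L
    best <- list(acc = -Inf, W = W, b = b)
    for (e in seq_len(epochs) - 1L) {
      lr_e <- lr * cosine_factor(e, epochs)
      ord <- sample(fit_idx)
      for (start in seq(1L, length(ord), batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, length(ord))]
        X <- features[idx, , drop = FALSE]
        logits <- X %*% W
        add_bias_inplace(logits, b)
        dlog <- smoothed_ce_grad(logits, labels[idx], label_smoothing)
        gW <- crossprod(X, dlog)
        gb <- colSums(dlog)
        t_step <- t_step + 1L
        bc1 <- 1 - 0.9^t_step
        bc2 <- 1 - 0.999^t_step
        m_W <- 0.9 * m_W + 0.1 * gW; v_W <- 0.999 * v_W + 0.001 * gW^2
        m_b <- 0.9 * m_b + 0.1 * gb; v_b <- 0.999 * v_b + 0.001 * gb^2
        W <- W - lr_e * (m_W / bc1) / (sqrt(v_W / bc2) + 1e-8)
        b <- b - lr_e * (m_b / bc1) / (sqrt(v_b / bc2) + 1e-8)
      }
      val_logits <- features[val_idx, , drop = FALSE] %*% W
      add_bias_inplace(val_logits, b)
      acc <- mean(max.col(val_logits, ties.method = "first") - 1L ==
                    labels[val_idx])
      if (acc > best$acc) best <- list(acc = acc, W = W, b = b)
    }
    list(W = best$W, b = best$b, val_acc = best$acc, epochs = epochs)
  })
}

predict_linear_probe <- function(probe, features) {
  logits <- features %*% probe$W
  add_bias_inplace(logits, probe$b)
  max.col(logits, ties.method = "first") - 1L
}

# inference-mode feature taps on a standardized x array
network_features <- function(params, bn, cfg, x,
                             level = c("local", "global", "fused"),
                             batch_size = 128L) {
  level <- match.arg(level)
  n <- dim(x)[1L]
  width <- if (level == "fused") cfg$feat_dim else cfg$d
  out <- matrix(0, n, width)
  for (start in seq(1L, n, batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fwd <- mgda_fwd(params, bn, x[idx, , , drop = FALSE], cfg,
                    training = FALSE)
    out[idx, ] <- switch(level,
      local = fwd$f_cnn,
      global = fwd$f_attn,
      fused = fwd$f_fused
    )
  }
  out
}

#' Extract features at a network tap point
#'
#' Inference-mode features at the CNN branch output (`"local"`, 128-d), the
#' attention branch output (`"global"`, 128-d), or the fused representation
#' (`"fused"`, 256-d for dual-branch models), after applying the model's
#' stored standardizer.
#'
#' @param model a fitted [mgda_net()].
#' @param ds an [enose_dataset()].
#' @param level `"local"`, `"global"` or `"fused"`.
#' @param stage `"final"` (default), `"stage1"` or `"stage2"` — which
#'   checkpoint's parameters to tap.
#' @return a feature matrix with one row per sample.
#' @export
extract_level_features <- function(model, ds,
                                   level = c("local", "global", "fused"),
                                   stage = c("final", "stage1", "stage2")) {
  level <- match.arg(level)
  stage <- match.arg(stage)
  cfg <- if (stage == "final") model$cfg else model$source_cfg
  pb <- switch(stage,
    final = list(params = model$params, bn = model$bn),
    stage1 = model$checkpoints$stage1,
    stage2 = model$checkpoints$stage2
  )
  if (is.null(pb)) stop("no ", stage, " checkpoint stored for this model")
  if (level == "local" && !cfg$use_cnn) stop("model has no CNN branch")
  if (level == "global" && !cfg$use_attn) stop("model has no attention branch")
  x <- standardize_dataset(ds, model$standardizer)$x
  network_features(pb$params, pb$bn, cfg, x, level)
}

#' Evaluate a fitted model on a labeled test set
#'
#' Inference-mode predictions followed by the full five-metric report; no
#' parameter is updated.
#'
#' @param model a fitted [mgda_net()].
#' @param test a labeled [enose_dataset()] with the model's target label
#'   space.
#' @return a [metrics_report()].
#' @export
evaluate_model <- function(model, test) {
  if (test$n_classes != model$n_target_classes) {
    stop("label-space mismatch: model predicts ", model$n_target_classes,
         " classes, test set has ", test$n_classes)
  }
  pred <- predict(model, test)
  metrics_report(test$class_label, pred, test$n_classes)
}

#' Predict target classes for new measurements
#'
#' @param object a fitted [mgda_net()].
#' @param newdata an [enose_dataset()].
#' @param type `"class"` for 0-based labels, `"prob"` for softmax
#'   probabilities (class-probability output is unavailable for the
#'   linear-probe variant, which predicts labels directly).
#' @param ... unused.
#' @return integer labels or a probability matrix.
#' @export
predict.mgda_net <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- standardize_dataset(newdata, object$standardizer)$x
  if (!is.null(object$probe)) {
    feats <- network_features(object$params, object$bn, object$cfg, x, "fused")
    if (type == "prob") {
      stop("probability output is not available for the linear-probe variant")
    }
    return(predict_linear_probe(object$probe, feats))
  }
  if (type == "class") {
    return(predict_labels(object$params, object$bn, object$cfg, x))
  }
  n <- dim(x)[1L]
  out <- matrix(0, n, object$cfg$n_classes)
  for (start in seq(1L, n, 128L)) {
    idx <- start:min(start + 127L, n)
    fwd <- mgda_fwd(object$params, object$bn, x[idx, , , drop = FALSE],
                    object$cfg, training = FALSE)
    out[idx, ] <- softmax_rows(fwd$logits)
  }
  out
}

#' @export
print.mgda_net <- function(x, ...) {
  cat("<mgda_net> variant:", x$variant, "\n")
  cat("  target classes:", x$n_target_classes,
      " | seed:", x$seed, "\n")
  cat("  stages run: pretrain(", x$epochs[["pretrain"]], ")",
      if (!is.null(x$checkpoints$stage2)) {
        paste0(" align(", x$epochs[["align"]], ")")
      } else {
        " [no alignment]"
      },
      if (is.null(x$probe)) {
        paste0(" finetune(", x$epochs[["finetune"]], ")")
      } else {
        " [linear probe]"
      },
      "\n", sep = "")
  if (!is.null(x$test_metrics)) {
    cat(sprintf("  test accuracy: %.4f (kappa %.4f)\n",
                x$test_metrics$overall_accuracy, x$test_metrics$kappa))
  }
  invisible(x)
}

#' @export
summary.mgda_net <- function(object, ...) {
  out <- list(
    variant = object$variant,
    n_parameters = n_parameters(object),
    stage1_best_epoch = object$checkpoints$stage1$best_epoch,
    stage1_val_acc = object$checkpoints$stage1$best_val_acc,
    test_metrics = object$test_metrics
  )
  class(out) <- "summary.mgda_net"
  out
}

#' @export
print.summary.mgda_net <- function(x, ...) {
  cat("MGDA-Net fit (variant:", x$variant, ")\n")
  cat("  trainable parameters:", x$n_parameters, "\n")
  cat("  stage-1 best val accuracy:", format(x$stage1_val_acc, digits = 4),
      "at epoch", x$stage1_best_epoch, "\n")
  if (!is.null(x$test_metrics)) print(x$test_metrics)
  invisible(x)
}

#' Number of trainable parameters
#' @param model a fitted [mgda_net()].
#' @param include_discriminators count discriminator weights too.
#' @return integer parameter count.
#' @export
n_parameters <- function(model, include_discriminators = FALSE) {
  nms <- names(model$params)
  if (!include_discriminators) {
    nms <- nms[!startsWith(nms, "dloc") & !startsWith(nms, "dglob")]
  }
  sum(vapply(model$params[nms], length, 0L))
}

#' Plot training history
#'
#' Base-graphics curves of the per-epoch training loss and validation
#' accuracy for the supervised stages.
#'
#' @param x a fitted [mgda_net()].
#' @param ... passed to [plot()].
#' @export
plot.mgda_net <- function(x, ...) {
  hs <- Filter(Negate(is.null), x$history[c("stage1", "stage3")])
  if (length(hs) == 0L) {
    stop("no supervised training history to plot")
  }
  op <- graphics::par(mfrow = c(1, length(hs)))
  on.exit(graphics::par(op))
  for (nm in names(hs)) {
    h <- hs[[nm]]
    plot(h$epoch, h$val_acc, type = "l", ylim = c(0, 1),
         xlab = "epoch", ylab = "validation accuracy", main = nm, ...)
    graphics::lines(h$epoch, h$loss / max(h$loss), lty = 2)
    graphics::legend("bottomright", legend = c("val accuracy",
                                               "loss (scaled)"),
                     lty = 1:2, bty = "n")
  }
  invisible(x)
}
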