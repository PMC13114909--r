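# The three-stage transfer protocol: source pretraining, multi-granularity
# adversarial alignment, and target fine-tuning with a swapped classifier
# head and differential learning rates.

#' Loss and schedule configuration
#'
#' @param label_smoothing cross-entropy smoothing `eps`.
#' @param center_weight `lambda_c`, weight of the center loss in the stage
#'   1/3 objective.
#' @param domain_weight `lambda_d`, weight of the adversarial losses in the
#'   stage-2 objective.
#' @param center_lr learning rate of the dedicated center SGD optimizer.
#' @param lambda_local_max,lambda_global_max reversal-intensity maxima of the
#'   local and global discriminators.
#' @return a plain list.
#' @export
loss_config <- function(label_smoothing = 0.05, center_weight = 0.01,
                        domain_weight = 0.5, center_lr = 0.5,
                        lambda_local_max = 0.2, lambda_global_max = 0.1) {
  list(label_smoothing = label_smoothing, center_weight = center_weight,
       domain_weight = domain_weight, center_lr = center_lr,
       lambda_local_max = lambda_local_max,
       lambda_global_max = lambda_global_max)
}

# inference-mode class predictions for a standardized x array
predict_labels <- function(params, bn, cfg, x, batch_size = 128L) {
  n <- dim(x)[1L]
  out <- integer(n)
  for (start in seq(1L, n, batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fwd <- mgda_fwd(params, bn, x[idx, , , drop = FALSE], cfg, training = FALSE)
    out[idx] <- max.col(fwd$logits, ties.method = "first") - 1L
  }
  out
}

accuracy_on <- function(params, bn, cfg, x, y) {
  mean(predict_labels(params, bn, cfg, x) == y)
}

# Supervised training shared by Stages 1 and 3: smoothed CE + weighted center
# loss, Adam with per-group cosine-annealed learning rates, per-epoch
# stratified validation accuracy and best-checkpoint selection.
train_supervised <- function(params, bn, cfg, x_fit, y_fit, x_val, y_val,
                             epochs, group_lrs, batch_size, losses, seed,
                             stage_tag, centers = NULL) {
  trainable <- setdiff(names(params),
                       names(params)[startsWith(names(params), "dloc") |
                                     startsWith(names(params), "dglob")])
  opt <- adam_init(params, trainable)
  if (is.null(centers)) centers <- matrix(0, cfg$n_classes, 128L)
  n <- dim(x_fit)[1L]
  best <- list(val_acc = -Inf, params = params, bn = bn, epoch = 0L,
               centers = centers)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        ce = numeric(0), center = numeric(0),
                        val_acc = numeric(0), lr_factor = numeric(0))
  with_seed(derive_seed(seed, stage_tag), {
    for (e in seq_len(epochs) - 1L) {
      fac <- cosine_factor(e, epochs)
      lrs <- lr_map(trainable, group_lrs, fac)
      ord <- sample.int(n)
      ep_loss <- 0
      ep_ce <- 0
      ep_ctr <- 0
      nb <- 0L
      for (start in seq(1L, n, batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        xb <- x_fit[idx, , , drop = FALSE]
        yb <- y_fit[idx]
        fwd <- mgda_fwd(params, bn, xb, cfg, training = TRUE)
        bn <- fwd$bn
        ce <- smoothed_cross_entropy(fwd$logits, yb, losses$label_smoothing)
        ctr <- center_loss(fwd$h, yb, centers)
        dlogits <- smoothed_ce_grad(fwd$logits, yb, losses$label_smoothing)
        dh <- losses$center_weight * center_loss_grad_h(fwd$h, yb, centers)
        grads <- mgda_bwd(fwd, dlogits, dh, params, cfg)
        st <- adam_step(params, grads, opt, lrs)
        params <- st$params
        opt <- st$state
        centers <- update_centers(fwd$h, yb, centers, losses$center_lr)
        ep_loss <- ep_loss + stage1_loss(ce, ctr, losses$center_weight)
        ep_ce <- ep_ce + ce
        ep_ctr <- ep_ctr + ctr
        nb <- nb + 1L
      }
      val_acc <- accuracy_on(params, bn, cfg, x_val, y_val)
      history <- rbind(history, data.frame(
        epoch = e, loss = ep_loss / nb, ce = ep_ce / nb,
        center = ep_ctr / nb, val_acc = val_acc, lr_factor = fac
      ))
      if (val_acc > best$val_acc) {
        best <- list(val_acc = val_acc, params = params, bn = bn,
                     epoch = e, centers = centers)
      }
    }
  })
  list(params = best$params, bn = bn_copy(best$bn), centers = best$centers,
       best_epoch = best$epoch, best_val_acc = best$val_acc,
       history = history, last_params = params, last_bn = bn)
}

bn_copy <- function(bn) bn  # R copy semantics; explicit for readability

#' Stage 1: source-domain pretraining
#'
#' Trains the full network on labeled source data with the smoothed
#' cross-entropy plus center-loss objective, Adam (lr 1e-3) with cosine
#' annealing, splitting off a stratified 20% validation subset and retaining
#' the checkpoint with the highest source validation accuracy.
#'
#' @param source an [enose_dataset()] (already dataset-standardized).
#' @param cfg an [mgda_config()] sized to the source class count.
#' @param params,bn as from [init_mgda_params()].
#' @param epochs training epochs (protocol default 200).
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size.
#' @param val_fraction stratified validation fraction.
#' @param losses a [loss_config()].
#' @param seed integer seed.
#' @return a checkpoint list: `params`, `bn`, `centers`, `best_epoch`,
#'   `best_val_acc`, `history`, `stage`, `seed`.
#' @export
pretrain_source <- function(source, cfg, params, bn, epochs = 200L,
                            lr = 1e-3, batch_size = 32L, val_fraction = 0.2,
                            losses = loss_config(), seed = 1L) {
  sp <- stratified_validation_split(source, val_fraction,
                                    derive_seed(seed, "stage1_val"))
  group_lrs <- c(cnn = lr, attn = lr, fusion = lr, classifier = lr)
  out <- train_supervised(
    params, bn, cfg,
    x_fit = sp$fit$x, y_fit = sp$fit$class_label,
    x_val = sp$val$x, y_val = sp$val$class_label,
    epochs = epochs, group_lrs = group_lrs, batch_size = batch_size,
    losses = losses, seed = seed, stage_tag = "stage1"
  )
  c(out, list(stage = "pretrain", seed = seed, epochs = epochs,
              fit_ids = sp$fit$sample_id, val_ids = sp$val$sample_id))
}

#' Stage 2: multi-granularity adversarial alignment
#'
#' Jointly trains the feature extractors (and classifier, through the
#' source classification term) against the two domain discriminators. Each
#' step draws equal-size mini-batches from source and target (the smaller
#' domain's loader cycles); target class labels are never read. The
#' extractor optimizer runs at `lr_extractor`, the discriminators at
#' `lr_disc`; the reversal intensities follow the sigmoid schedule up to
#' their maxima. Returns the last-epoch checkpoint.
#'
#' @param ckpt Stage-1 checkpoint (`params`, `bn`, `centers`).
#' @param source labeled source dataset (standardized).
#' @param target_train target-domain training dataset (labels ignored).
#' @param cfg an [mgda_config()].
#' @param epochs training epochs (protocol default 200).
#' @param lr_extractor,lr_disc component learning rates.
#' @param batch_size per-domain mini-batch size.
#' @param use_local,use_global enable each granularity's discriminator
#'   (single-granularity ablations disable one).
#' @param losses a [loss_config()].
#' @param seed integer seed.
#' @return a checkpoint list (last epoch), with a per-epoch `history`.
#' @export
adversarial_align <- function(ckpt, source, target_train, cfg, epochs = 200L,
                              lr_extractor = 2e-4, lr_disc = 1e-3,
                              batch_size = 32L, use_local = TRUE,
                              use_global = TRUE, losses = loss_config(),
                              seed = 1L) {
  if (length(target_train) < 1L) stop("target training set is empty")
  if (!cfg$use_cnn) use_local <- use_local && FALSE
  if (!cfg$use_attn) use_global <- use_global && FALSE
  params <- ckpt$params
  bn <- ckpt$bn
  ext_names <- names(params)[!startsWith(names(params), "dloc") &
                             !startsWith(names(params), "dglob")]
  disc_names <- character(0)
  if (use_local) {
    disc_names <- c(disc_names,
                    names(params)[startsWith(names(params), "dloc")])
  }
  if (use_global) {
    disc_names <- c(disc_names,
                    names(params)[startsWith(names(params), "dglob")])
  }
  opt_ext <- adam_init(params, ext_names)
  opt_disc <- if (length(disc_names)) adam_init(params, disc_names) else NULL
  xs <- source$x
  ys <- source$class_label
  xt <- target_train$x
  n_s <- dim(xs)[1L]
  n_t <- dim(xt)[1L]
  steps <- ceiling(max(n_s, n_t) / batch_size)
  history <- data.frame(epoch = integer(0), ce = numeric(0),
                        dom_local = numeric(0), dom_global = numeric(0),
                        lambda_local = numeric(0), lambda_global = numeric(0))
  with_seed(derive_seed(seed, "stage2"), {
    for (e in seq_len(epochs) - 1L) {
      lam_l <- lambda_schedule(e, epochs, losses$lambda_local_max)
      lam_g <- lambda_schedule(e, epochs, losses$lambda_global_max)
      fac <- cosine_factor(e, epochs)
      lrs_ext <- lr_map(ext_names,
                        c(cnn = lr_extractor, attn = lr_extractor,
                          fusion = lr_extractor, classifier = lr_extractor),
                        fac)
      lrs_disc <- lr_map(disc_names,
                         c(disc_local = lr_disc, disc_global = lr_disc), fac)
      ord_s <- cycle_order(n_s, steps * batch_size)
      ord_t <- cycle_order(n_t, steps * batch_size)
      ep <- c(ce = 0, dl = 0, dg = 0)
      for (s in seq_len(steps)) {
        take <- (s - 1L) * batch_size + seq_len(batch_size)
        is <- ord_s[take]
        it <- ord_t[take]
        nb_s <- length(is)
        xb <- abind_rows(xs[is, , , drop = FALSE], xt[it, , , drop = FALSE])
        xn <- instance_normalize_array(xb)
        f_cnn <- NULL; f_attn <- NULL; ccache <- NULL; acache <- NULL
        if (cfg$use_cnn) {
          cb <- cnn_branch_fwd(params, bn, xn, cfg, TRUE)
          f_cnn <- cb$f; ccache <- cb$cache; bn <- cb$bn
        }
        if (cfg$use_attn) {
          ab <- attn_branch_fwd(params, bn, xn, cfg, TRUE)
          f_attn <- ab$f; acache <- ab$cache; bn <- ab$bn
        }
        src_rows <- seq_len(nb_s)
        hd <- head_fwd(params, bn,
                       if (is.null(f_cnn)) NULL else f_cnn[src_rows, , drop = FALSE],
                       if (is.null(f_attn)) NULL else f_attn[src_rows, , drop = FALSE],
                       cfg, TRUE)
        bn <- hd$bn
        ce <- smoothed_cross_entropy(hd$logits, ys[is], losses$label_smoothing)
        dlogits <- smoothed_ce_grad(hd$logits, ys[is], losses$label_smoothing)
        hb <- head_bwd(dlogits, NULL, params, hd$cache, cfg)
        grads <- hb$grads
        df_cnn_full <- if (cfg$use_cnn) matrix(0, nrow(f_cnn), cfg$d) else NULL
        df_attn_full <- if (cfg$use_attn) matrix(0, nrow(f_attn), cfg$d) else NULL
        if (!is.null(hb$df_cnn)) df_cnn_full[src_rows, ] <- hb$df_cnn
        if (!is.null(hb$df_attn)) df_attn_full[src_rows, ] <- hb$df_attn
        dl <- NA_real_
        dg <- NA_real_
        if (use_local) {
          adv <- domain_adversarial_loss(
            f_cnn[src_rows, , drop = FALSE],
            f_cnn[-src_rows, , drop = FALSE],
            params, cfg, "local", lam_l, training = TRUE
          )
          dl <- adv$loss
          ab2 <- domain_adversarial_bwd(adv)
          # lambda_d scales the whole adversarial term (Stage-2 objective)
          grads <- add_grads(grads, scale_grads(ab2$grads, losses$domain_weight))
          df_cnn_full <- df_cnn_full +
            losses$domain_weight * ab2$df_features
        }
        if (use_global) {
          adv <- domain_adversarial_loss(
            f_attn[src_rows, , drop = FALSE],
            f_attn[-src_rows, , drop = FALSE],
            params, cfg, "global", lam_g, training = TRUE
          )
          dg <- adv$loss
          ab2 <- domain_adversarial_bwd(adv)
          grads <- add_grads(grads, scale_grads(ab2$grads, losses$domain_weight))
          df_attn_full <- df_attn_full +
            losses$domain_weight * ab2$df_features
        }
        if (cfg$use_cnn) {
          grads <- c(grads, cnn_branch_bwd(df_cnn_full, ccache))
        }
        if (cfg$use_attn) {
          grads <- c(grads, attn_branch_bwd(df_attn_full, params, acache, cfg))
        }
        st <- adam_step(params, grads, opt_ext, lrs_ext)
        params <- st$params
        opt_ext <- st$state
        if (!is.null(opt_disc)) {
          st <- adam_step(params, grads, opt_disc, lrs_disc)
          params <- st$params
          opt_disc <- st$state
        }
        ep <- ep + c(ce, if (is.na(dl)) 0 else dl, if (is.na(dg)) 0 else dg)
      }
      history <- rbind(history, data.frame(
        epoch = e, ce = ep[1] / steps, dom_local = ep[2] / steps,
        dom_global = ep[3] / steps, lambda_local = lam_l,
        lambda_global = lam_g
      ))
    }
  })
  list(params = params, bn = bn, centers = ckpt$centers, history = history,
       stage = "align", seed = seed, epochs = epochs,
       use_local = use_local, use_global = use_global)
}

cycle_order <- function(n, len) {
  reps <- ceiling(len / n)
  ord <- unlist(lapply(seq_len(reps), function(i) sample.int(n)))
  ord[seq_len(len)]
}

abind_rows <- function(a, b) {
  out <- array(0, c(dim(a)[1L] + dim(b)[1L], dim(a)[2L], dim(a)[3L]))
  out[seq_len(dim(a)[1L]), , ] <- a
  out[dim(a)[1L] + seq_len(dim(b)[1L]), , ] <- b
  out
}

add_grads <- function(g, extra) {
  for (nm in names(extra)) {
    g[[nm]] <- if (is.null(g[[nm]])) extra[[nm]] else g[[nm]] + extra[[nm]]
  }
  g
}

scale_grads <- function(g, s) lapply(g, function(x) s * x)

#' Stage 3: target-domain fine-tuning
#'
#' Replaces the classifier head with a freshly initialised MLP sized to the
#' target class count, reinitialises the center matrix, and fine-tunes the
#' whole network on labeled target training data with differential learning
#' rates (branches 3e-5, fusion 5e-5, new classifier 1e-4), cosine annealing,
#' a stratified 20% validation split and best-validation checkpointing.
#'
#' @param ckpt Stage-2 (or Stage-1, for the no-adaptation ablation)
#'   checkpoint.
#' @param target_train labeled target training dataset (standardized).
#' @param n_target_classes target class count.
#' @param cfg the [mgda_config()] used so far (class count is replaced).
#' @param epochs training epochs (protocol default 300).
#' @param lr_branches,lr_fusion,lr_classifier differential learning rates.
#' @param batch_size mini-batch size.
#' @param val_fraction stratified validation fraction.
#' @param losses a [loss_config()].
#' @param seed integer seed.
#' @return a checkpoint list with the best-validation parameters and the new
#'   `cfg`.
#' @export
finetune_target <- function(ckpt, target_train, n_target_classes, cfg,
                            epochs = 300L, lr_branches = 3e-5,
                            lr_fusion = 5e-5, lr_classifier = 1e-4,
                            batch_size = 32L, val_fraction = 0.2,
                            losses = loss_config(), seed = 1L) {
  if (n_target_classes != target_train$n_classes) {
    stop("n_target_classes (", n_target_classes,
         ") does not match the target dataset (", target_train$n_classes, ")")
  }
  new_cfg <- cfg
  new_cfg$n_classes <- as.integer(n_target_classes)
  params <- ckpt$params
  bn <- ckpt$bn
  head <- with_seed(derive_seed(seed, "stage3_head"),
                    init_classifier_params(new_cfg))
  params[names(head$params)] <- head$params
  bn[names(head$bn)] <- head$bn
  centers <- matrix(0, n_target_classes, 128L)
  sp <- stratified_validation_split(target_train, val_fraction,
                                    derive_seed(seed, "stage3_val"))
  group_lrs <- c(cnn = lr_branches, attn = lr_branches, fusion = lr_fusion,
                 classifier = lr_classifier)
  out <- train_supervised(
    params, bn, new_cfg,
    x_fit = sp$fit$x, y_fit = sp$fit$class_label,
    x_val = sp$val$x, y_val = sp$val$class_label,
    epochs = epochs, group_lrs = group_lrs, batch_size = batch_size,
    losses = losses, seed = seed, stage_tag = "stage3", centers = centers
  )
  c(out, list(stage = "finetune", seed = seed, cfg = new_cfg,
              epochs = epochs, fit_ids = sp$fit$sample_id,
              val_ids = sp$val$sample_id))
}
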