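# Training objectives: label-smoothed cross-entropy, center loss with its
# dedicated SGD update, the binary domain-adversarial loss, the sigmoid
# reversal-intensity schedule, and the stage-level loss compositions.

# log-sum-exp stabilized row-wise softmax + log-softmax
softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

log_softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  z - log(rowSums(exp(z)))
}

#' Label-smoothed cross-entropy
#'
#' Mean over samples of `-sum_c ytilde_ic log p_ic` with smoothed targets
#' `ytilde_ic = (1 - eps) * 1(c = y_i) + eps / C` and `p` the softmax of the
#' logits. `eps = 0` recovers the standard one-hot cross-entropy.
#'
#' @param logits `n x C` matrix.
#' @param y integer 0-based labels.
#' @param eps smoothing parameter in `[0, 1)`.
#' @return scalar loss.
#' @export
smoothed_cross_entropy <- function(logits, y, eps = 0.05) {
  stopifnot(eps >= 0, eps < 1, all(is.finite(logits)))
  C <- ncol(logits)
  lp <- log_softmax_rows(logits)
  n <- nrow(logits)
  true_lp <- lp[cbind(seq_len(n), y + 1L)]
  # -( (1-eps) * log p_true + eps/C * sum_c log p_c )
  mean(-(1 - eps) * true_lp - eps / C * rowSums(lp))
}

# gradient of smoothed CE w.r.t. logits: (p - ytilde) / n
smoothed_ce_grad <- function(logits, y, eps = 0.05) {
  C <- ncol(logits)
  n <- nrow(logits)
  p <- softmax_rows(logits)
  yt <- matrix(eps / C, n, C)
  yt[cbind(seq_len(n), y + 1L)] <- yt[cbind(seq_len(n), y + 1L)] + (1 - eps)
  (p - yt) / n
}

#' Center loss
#'
#' Mean squared Euclidean distance between each penultimate feature and its
#' learnable class center, `(1/N) sum_i ||h_i - c_{y_i}||^2` — the
#' intra-class compactness regularizer.
#'
#' @param h `n x d` feature matrix.
#' @param y integer 0-based labels.
#' @param centers `C x d` center matrix.
#' @return scalar loss.
#' @export
center_loss <- function(h, y, centers) {
  if (any(y + 1L > nrow(centers))) {
    stop("label without a matching center row")
  }
  diff <- h - centers[y + 1L, , drop = FALSE]
  mean(rowSums(diff^2))
}

# gradient of the (unweighted) center loss w.r.t. h: 2/N (h - c_y)
center_loss_grad_h <- function(h, y, centers) {
  2 / nrow(h) * (h - centers[y + 1L, , drop = FALSE])
}

#' One SGD step on the class centers
#'
#' Plain gradient descent on the unweighted center loss with respect to the
#' centers only: `c_k <- c_k - lr * (2/N) sum_{i: y_i = k} (c_k - h_i)`.
#' Centers of classes absent from the batch are untouched. With `lr = 0.5`
#' and a single-sample batch the center lands exactly on `h`.
#'
#' @param h `n x d` feature batch.
#' @param y integer 0-based labels.
#' @param centers `C x d` center matrix.
#' @param lr center learning rate (default 0.5).
#' @return the updated center matrix.
#' @export
update_centers <- function(h, y, centers, lr = 0.5) {
  if (any(y + 1L > nrow(centers))) stop("label without a matching center row")
  n <- nrow(h)
  for (k in unique(y)) {
    rows <- which(y == k)
    ck <- centers[k + 1L, ]
    grad <- 2 / n * (length(rows) * ck - colSums(h[rows, , drop = FALSE]))
    centers[k + 1L, ] <- ck - lr * grad
  }
  centers
}

#' Domain-adversarial loss
#'
#' Binary cross-entropy of a granularity-specific domain discriminator on
#' features passed through a gradient reversal layer, with domain labels 0
#' (source) and 1 (target), averaged over the `n_s + n_t` samples:
#' `-(1/(n_s+n_t)) [ sum_i log(1 - D(f_i^s)) + sum_j log D(f_j^t) ]`.
#' Evaluated in logit space via softplus for numerical stability. Minimising
#' it trains the discriminator; the reversed gradient `-lambda` trains the
#' extractor adversarially.
#'
#' @param source_features `n_s x 128` matrix, `n_s >= 1`.
#' @param target_features `n_t x 128` matrix, `n_t >= 1`.
#' @param params network parameter list holding the discriminator weights.
#' @param cfg an [mgda_config()].
#' @param granularity `"local"` or `"global"` (selects the discriminator).
#' @param lambda reversal intensity, `>= 0`.
#' @param training training mode (enables discriminator dropout).
#' @return list with `loss`, the per-sample discriminator `logits`, the
#'   domain `labels`, and internal caches for the backward pass.
#' @export
domain_adversarial_loss <- function(source_features, target_features, params,
                                    cfg, granularity = c("local", "global"),
                                    lambda = 0, training = FALSE) {
  granularity <- match.arg(granularity)
  if (is.null(source_features) || nrow(source_features) < 1L ||
      is.null(target_features) || nrow(target_features) < 1L) {
    stop("both domains must be present in an adversarial batch")
  }
  tag <- if (granularity == "local") "dloc" else "dglob"
  f <- grl_apply(rbind(source_features, target_features), lambda)
  d <- disc_fwd(params, tag, f, cfg, training)
  labels <- c(rep(0, nrow(source_features)), rep(1, nrow(target_features)))
  # BCE in logit space: softplus(z) - label * z
  z <- d$logit
  loss <- mean(softplus(z) - labels * z)
  list(loss = loss, logits = z, labels = labels, cache = d$cache,
       lambda = lambda, n_source = nrow(source_features))
}

softplus <- function(z) ifelse(z > 30, z, log1p(exp(z)))

# backward through a domain_adversarial_loss evaluation: returns discriminator
# parameter grads and the GRL-reversed gradient w.r.t. the input features
domain_adversarial_bwd <- function(adv) {
  n <- length(adv$logits)
  dz <- (1 / (1 + exp(-adv$logits)) - adv$labels) / n
  db <- disc_bwd(dz, adv$cache)
  list(grads = db$grads,
       df_features = grl_backward(db$df, adv$lambda),
       df_disc_input = db$df)
}

#' Reversal-intensity schedule
#'
#' `lambda(e) = lambda_max * (2 / (1 + exp(-10 e / E)) - 1)`: zero at epoch 0,
#' rising along a sigmoid to just below `lambda_max` at the final epoch. `e`
#' counts completed epochs starting at 0 and the value is updated once per
#' epoch.
#'
#' @param e current epoch, `0 <= e <= E`.
#' @param E total epochs, `>= 1`.
#' @param lambda_max asymptotic intensity.
#' @return the scheduled intensity.
#' @export
lambda_schedule <- function(e, E, lambda_max) {
  if (E < 1) stop("E must be >= 1")
  if (e < 0 || e > E) stop("e must lie in [0, E]")
  lambda_max * (2 / (1 + exp(-10 * e / E)) - 1)
}

#' Stage-loss compositions
#'
#' Stage 1/3 objective `L_cls + lambda_c * L_center`; Stage 2 objective
#' `L_cls_source + lambda_d * (L_domain_local + L_domain_global)`.
#'
#' @param L_cls,L_center,L_cls_source,L_dom_local,L_dom_global component
#'   losses.
#' @param lambda_c center-loss weight (default 0.01).
#' @param lambda_d domain-loss weight (default 0.5).
#' @return scalar total loss.
#' @export
stage1_loss <- function(L_cls, L_center, lambda_c = 0.01) {
  L_cls + lambda_c * L_center
}

#' @rdname stage1_loss
#' @export
stage2_loss <- function(L_cls_source, L_dom_local, L_dom_global,
                        lambda_d = 0.5) {
  L_cls_source + lambda_d * (L_dom_local + L_dom_global)
}
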