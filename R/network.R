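# MGDA-Net architecture: a CNN branch (three conv blocks -> 128-d local
# feature), a self-attention branch (2-layer pre-LN transformer encoder ->
# 128-d global feature), a sigmoid-gated fusion to a 256-d representation,
# an MLP classifier with a 128-d penultimate feature, and two
# domain discriminators fed through gradient reversal.

#' Network architecture configuration
#'
#' @param n_classes classifier output size.
#' @param use_cnn,use_attn enable the local (CNN) / global (attention)
#'   branch; disabling one gives the single-branch ablation variants, whose
#'   128-d branch feature feeds the classifier directly.
#' @param fusion `"gate"` (learnable sigmoid gate), `"concat"` (plain
#'   concatenation + projection ablation) or `"single"` (single-branch
#'   bypass, set automatically).
#' @param dropout_attn dropout inside the encoder sublayers.
#' @param dropout_cls classifier dropout.
#' @param dropout_disc discriminator dropout.
#' @return an object of class `mgda_config`.
#' @export
mgda_config <- function(n_classes, use_cnn = TRUE, use_attn = TRUE,
                        fusion = c("gate", "concat", "single"),
                        dropout_attn = 0.1, dropout_cls = 0.5,
                        dropout_disc = 0.3) {
  if (n_classes < 2L) stop("n_classes must be >= 2")
  fusion <- match.arg(fusion)
  if (!use_cnn && !use_attn) stop("at least one branch must be enabled")
  if (!use_cnn || !use_attn) fusion <- "single"
  structure(
    list(
      n_classes = as.integer(n_classes),
      use_cnn = use_cnn, use_attn = use_attn, fusion = fusion,
      d = 128L,              # branch feature width
      dm = 64L,              # encoder model width
      heads = 4L, dk = 16L,  # per-head width dm / heads
      ff = 256L,             # encoder feed-forward width
      n_layers = 2L,
      feat_dim = if (fusion == "single") 128L else 256L,
      conv_filters = c(32L, 64L, 128L),
      conv_kernels = c(5L, 5L, 3L),
      dropout_attn = dropout_attn, dropout_cls = dropout_cls,
      dropout_disc = dropout_disc
    ),
    class = "mgda_config"
  )
}

# fan-in He initialisation for ReLU layers, Glorot for linear maps
he_mat <- function(nin, nout) matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
glorot_mat <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialise network parameters
#'
#' Standard fan-in schemes throughout; the fusion gate's output layer is
#' zero-initialised so training starts at alpha = 0.5 exactly.
#'
#' @param cfg an [mgda_config()].
#' @param seed integer seed.
#' @return list with `params` (flat named list) and `bn` (running statistics).
#' @export
init_mgda_params <- function(cfg, seed = 1L) {
  with_seed(derive_seed(seed, "init"), {
    p <- list()
    bn <- list()
    add_bn <- function(name, width) {
      p[[paste0(name, "_g")]] <<- rep(1, width)
      p[[paste0(name, "_b")]] <<- rep(0, width)
      bn[[name]] <<- list(rm = rep(0, width), rv = rep(1, width))
    }
    if (cfg$use_cnn) {
      f <- cfg$conv_filters
      k <- cfg$conv_kernels
      chain <- c(C_SENSORS, f)
      for (i in 1:3) {
        nin <- chain[i] * k[i]
        p[[paste0("conv", i, "_W")]] <-
          matrix(rnorm(f[i] * nin, 0, sqrt(2 / nin)), f[i], nin)
        p[[paste0("conv", i, "_b")]] <- rep(0, f[i])
        add_bn(paste0("cbn", i), f[i])
      }
      p$cfc_W <- he_mat(f[3], cfg$d)
      p$cfc_b <- rep(0, cfg$d)
      add_bn("cfcbn", cfg$d)
    }
    if (cfg$use_attn) {
      p$ain_W <- he_mat(C_SENSORS, cfg$dm)
      p$ain_b <- rep(0, cfg$dm)
      for (l in seq_len(cfg$n_layers)) {
        pre <- paste0("l", l, "_")
        p[[paste0(pre, "ln1_g")]] <- rep(1, cfg$dm)
        p[[paste0(pre, "ln1_b")]] <- rep(0, cfg$dm)
        for (nm in c("Wq", "Wk", "Wv", "Wo")) {
          p[[paste0(pre, nm)]] <- glorot_mat(cfg$dm, cfg$dm)
        }
        for (nm in c("bq", "bk", "bv", "bo")) {
          p[[paste0(pre, nm)]] <- rep(0, cfg$dm)
        }
        p[[paste0(pre, "ln2_g")]] <- rep(1, cfg$dm)
        p[[paste0(pre, "ln2_b")]] <- rep(0, cfg$dm)
        p[[paste0(pre, "ff1_W")]] <- he_mat(cfg$dm, cfg$ff)
        p[[paste0(pre, "ff1_b")]] <- rep(0, cfg$ff)
        p[[paste0(pre, "ff2_W")]] <- glorot_mat(cfg$ff, cfg$dm)
        p[[paste0(pre, "ff2_b")]] <- rep(0, cfg$dm)
      }
      p$afc_W <- he_mat(cfg$dm, cfg$d)
      p$afc_b <- rep(0, cfg$d)
      add_bn("afcbn", cfg$d)
    }
    if (cfg$fusion == "gate") {
      p$gate1_W <- he_mat(2L * cfg$d, 64L)
      p$gate1_b <- rep(0, 64L)
      p$gate2_W <- matrix(0, 64L, 1L)   # zero init -> alpha = 0.5 at start
      p$gate2_b <- 0
    }
    if (cfg$fusion != "single") {
      p$fproj_W <- he_mat(2L * cfg$d, 256L)
      p$fproj_b <- rep(0, 256L)
      add_bn("fbn", 256L)
    }
    head <- init_classifier_params(cfg)
    p[names(head$params)] <- head$params
    bn[names(head$bn)] <- head$bn
    for (tag in c("dloc", "dglob")) {
      p[[paste0(tag, "_W1")]] <- he_mat(cfg$d, 128L)
      p[[paste0(tag, "_b1")]] <- rep(0, 128L)
      p[[paste0(tag, "_W2")]] <- he_mat(128L, 64L)
      p[[paste0(tag, "_b2")]] <- rep(0, 64L)
      p[[paste0(tag, "_W3")]] <- he_mat(64L, 1L)
      p[[paste0(tag, "_b3")]] <- 0
    }
    list(params = p, bn = bn)
  })
}

# classifier head parameters alone (used for the Stage-3 head swap); draws
# from the current RNG stream
init_classifier_params <- function(cfg) {
  p <- list(
    cls1_W = he_mat(cfg$feat_dim, 128L),
    cls1_b = rep(0, 128L),
    clsbn_g = rep(1, 128L),
    clsbn_b = rep(0, 128L),
    cls2_W = glorot_mat(128L, cfg$n_classes),
    cls2_b = rep(0, cfg$n_classes)
  )
  bn <- list(clsbn = list(rm = rep(0, 128L), rv = rep(1, 128L)))
  list(params = p, bn = bn)
}

# parameter name -> optimizer group
param_group <- function(name) {
  if (grepl("^(conv|cbn|cfc)", name)) return("cnn")
  if (grepl("^(ain|l[0-9]+_|afc)", name)) return("attn")
  if (grepl("^(gate|fproj|fbn)", name)) return("fusion")
  if (grepl("^cls", name)) return("classifier")
  if (grepl("^dloc", name)) return("disc_local")
  if (grepl("^dglob", name)) return("disc_global")
  stop("unknown parameter: ", name)
}

#' Sinusoidal positional encoding
#'
#' Entry `(pos, 2i)` is `sin(pos / 10000^(2i/d_m))` and `(pos, 2i+1)` the
#' matching cosine, for 0-based `pos` and `i`; all entries lie in `[-1, 1]`.
#'
#' @param T sequence length.
#' @param d_m model dimension (must be even).
#' @return a `T x d_m` matrix.
#' @export
positional_encoding <- function(T, d_m) {
  if (d_m %% 2L != 0L) stop("d_m must be even")
  pos <- 0:(T - 1L)
  i <- 0:(d_m / 2L - 1L)
  angle <- outer(pos, 1 / 10000^(2 * i / d_m))
  pe <- matrix(0, T, d_m)
  pe[, 2L * i + 1L] <- sin(angle)
  pe[, 2L * i + 2L] <- cos(angle)
  pe
}

#' Gradient reversal layer
#'
#' Identity in the forward pass; during backpropagation the gradient flowing
#' back through it is multiplied by `-lambda`. In this implementation the
#' forward pass is literally the identity and the training loop applies the
#' `-lambda` factor to the discriminator's input gradient before it reaches
#' the feature extractor (see [grl_backward()]), which is the standard
#' autograd-free realisation of the layer.
#'
#' @param f features (any numeric array).
#' @param lambda reversal intensity, `>= 0`.
#' @return `f`, unchanged.
#' @export
grl_apply <- function(f, lambda) {
  stopifnot(lambda >= 0)
  f
}

#' @rdname grl_apply
#' @param df gradient arriving from the discriminator side.
#' @return `-lambda * df`, the gradient the feature extractor receives.
#' @export
grl_backward <- function(df, lambda) {
  stopifnot(lambda >= 0)
  -lambda * df
}

## ---- CNN branch -------------------------------------------------------------

cnn_branch_fwd <- function(p, bn, x, cfg, training) {
  n <- dim(x)[1L]
  caches <- list(n = n)
  xm <- matrix(aperm(x, c(2L, 1L, 3L)), C_SENSORS, n * T_STEPS)
  T <- T_STEPS
  k <- cfg$conv_kernels
  for (i in 1:3) {
    cv <- conv1d_fwd(xm, p[[paste0("conv", i, "_W")]],
                     p[[paste0("conv", i, "_b")]], n, T, k[i],
                     pad = (k[i] - 1L) %/% 2L)
    bname <- paste0("cbn", i)
    bno <- bnr_fwd(cv$y, p[[paste0(bname, "_g")]], p[[paste0(bname, "_b")]],
                   bn[[bname]]$rm, bn[[bname]]$rv, training)
    bn[[bname]]$rm <- bno$rm
    bn[[bname]]$rv <- bno$rv
    rl <- relu_fwd(bno$y)
    mp <- maxpool2_fwd(rl$y, n, T)
    caches[[paste0("conv", i)]] <- cv$cache
    caches[[paste0("bn", i)]] <- bno$cache
    caches[[paste0("relu", i)]] <- rl$cache
    caches[[paste0("pool", i)]] <- mp$cache
    xm <- mp$y
    T <- T %/% 2L
  }
  ap <- avgpool_fwd(xm, n, T)
  fc <- fc_fwd(ap$y, p$cfc_W, p$cfc_b)
  bno <- bnc_fwd(fc$y, p$cfcbn_g, p$cfcbn_b, bn$cfcbn$rm, bn$cfcbn$rv, training)
  bn$cfcbn$rm <- bno$rm
  bn$cfcbn$rv <- bno$rv
  rl <- relu_fwd(bno$y)
  caches$avg <- ap$cache
  caches$fc <- fc$cache
  caches$fcbn <- bno$cache
  caches$fcrelu <- rl$cache
  list(f = rl$y, cache = caches, bn = bn)
}

cnn_branch_bwd <- function(df, cache) {
  g <- list()
  d <- relu_bwd(df, cache$fcrelu)
  bb <- bnc_bwd(d, cache$fcbn)
  g$cfcbn_g <- bb$dg
  g$cfcbn_b <- bb$db
  fb <- fc_bwd(bb$dx, cache$fc)
  g$cfc_W <- fb$dW
  g$cfc_b <- fb$db
  dxm <- avgpool_bwd(fb$dx, cache$avg)
  for (i in 3:1) {
    dxm <- maxpool2_bwd(dxm, cache[[paste0("pool", i)]])
    dxm <- relu_bwd(dxm, cache[[paste0("relu", i)]])
    bb <- bnr_bwd(dxm, cache[[paste0("bn", i)]])
    g[[paste0("cbn", i, "_g")]] <- bb$dg
    g[[paste0("cbn", i, "_b")]] <- bb$db
    cb <- conv1d_bwd(bb$dx, cache[[paste0("conv", i)]])
    g[[paste0("conv", i, "_W")]] <- cb$dW
    g[[paste0("conv", i, "_b")]] <- cb$db
    dxm <- cb$dx
  }
  g
}

## ---- attention branch -------------------------------------------------------

# One pre-layer-norm encoder layer; the heavy lifting happens in one C++
# call per direction (see src/encoder.cpp), with intermediates held in an
# external-pointer cache.
encoder_layer_params <- function(p, pre) {
  nms <- c("ln1_g", "ln1_b", "Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
           "ln2_g", "ln2_b", "ff1_W", "ff1_b", "ff2_W", "ff2_b")
  stats::setNames(p[paste0(pre, nms)], nms)
}

encoder_layer_fwd <- function(p, pre, H, n, cfg, training) {
  out <- enc_layer_forward_cpp(H, encoder_layer_params(p, pre), n, T_STEPS,
                               cfg$heads, cfg$dk, cfg$dropout_attn, training)
  list(y = out$y, cache = out$cache)
}

encoder_layer_bwd <- function(dH3, p, pre, cache, cfg) {
  out <- enc_layer_backward_cpp(dH3, cache, encoder_layer_params(p, pre))
  g <- out[names(out) != "dx"]
  names(g) <- paste0(pre, names(g))
  # arma row vectors come back as 1 x d matrices; flatten bias/gain gradients
  g <- lapply(g, function(x) {
    if (is.matrix(x) && nrow(x) == 1L && ncol(x) > 1L) as.vector(x) else x
  })
  list(dx = out$dx, grads = g)
}

attn_branch_fwd <- function(p, bn, x, cfg, training) {
  n <- dim(x)[1L]
  # rows sample-major, time fastest within a sample
  Xt <- matrix(aperm(x, c(3L, 1L, 2L)), n * T_STEPS, C_SENSORS)
  inp <- fc_fwd(Xt, p$ain_W, p$ain_b)
  inr <- relu_fwd(inp$y)
  pe <- positional_encoding(T_STEPS, cfg$dm)
  H <- inr$y + pe[rep(seq_len(T_STEPS), n), ]
  caches <- list(n = n, inp = inp$cache, inr = inr$cache)
  for (l in seq_len(cfg$n_layers)) {
    el <- encoder_layer_fwd(p, paste0("l", l, "_"), H, n, cfg, training)
    caches[[paste0("enc", l)]] <- el$cache
    H <- el$y
  }
  # temporal mean pooling per sample
  grp <- rep(seq_len(n), each = T_STEPS)
  pooled <- rowsum(H, grp, reorder = FALSE) / T_STEPS
  dimnames(pooled) <- NULL
  fc <- fc_fwd(pooled, p$afc_W, p$afc_b)
  bno <- bnc_fwd(fc$y, p$afcbn_g, p$afcbn_b, bn$afcbn$rm, bn$afcbn$rv, training)
  bn$afcbn$rm <- bno$rm
  bn$afcbn$rv <- bno$rv
  rl <- relu_fwd(bno$y)
  caches$fc <- fc$cache
  caches$fcbn <- bno$cache
  caches$fcrelu <- rl$cache
  list(f = rl$y, cache = caches, bn = bn)
}

attn_branch_bwd <- function(df, p, cache, cfg) {
  g <- list()
  n <- cache$n
  d <- relu_bwd(df, cache$fcrelu)
  bb <- bnc_bwd(d, cache$fcbn)
  g$afcbn_g <- bb$dg
  g$afcbn_b <- bb$db
  fb <- fc_bwd(bb$dx, cache$fc)
  g$afc_W <- fb$dW
  g$afc_b <- fb$db
  # un-pool: every time step gets dpooled / T
  dH <- fb$dx[rep(seq_len(n), each = T_STEPS), , drop = FALSE] / T_STEPS
  for (l in rev(seq_len(cfg$n_layers))) {
    eb <- encoder_layer_bwd(dH, p, paste0("l", l, "_"),
                            cache[[paste0("enc", l)]], cfg)
    g[names(eb$grads)] <- eb$grads
    dH <- eb$dx
  }
  d <- relu_bwd(dH, cache$inr)
  fb <- fc_bwd(d, cache$inp)
  g$ain_W <- fb$dW
  g$ain_b <- fb$db
  g
}

## ---- fusion + classifier head ----------------------------------------------

head_fwd <- function(p, bn, f_cnn, f_attn, cfg, training) {
  ca <- list()
  if (cfg$fusion == "single") {
    feat <- if (cfg$use_cnn) f_cnn else f_attn
    alpha <- NULL
    fused <- feat
  } else {
    cat_f <- cbind(f_cnn, f_attn)
    if (cfg$fusion == "gate") {
      g1 <- fc_fwd(cat_f, p$gate1_W, p$gate1_b)
      g1r <- relu_fwd(g1$y)
      g2 <- fc_fwd(g1r$y, p$gate2_W, p$gate2_b)
      alpha <- unname(1 / (1 + exp(-g2$y[, 1L])))
      win <- cbind(alpha * f_cnn, (1 - alpha) * f_attn)
      ca$gate <- list(g1 = g1$cache, g1r = g1r$cache, g2 = g2$cache,
                      alpha = alpha, f_cnn = f_cnn, f_attn = f_attn)
    } else {
      alpha <- NULL
      win <- cat_f
    }
    pr <- fc_fwd(win, p$fproj_W, p$fproj_b)
    bno <- bnc_fwd(pr$y, p$fbn_g, p$fbn_b, bn$fbn$rm, bn$fbn$rv, training)
    bn$fbn$rm <- bno$rm
    bn$fbn$rv <- bno$rv
    rl <- relu_fwd(bno$y)
    fused <- rl$y
    ca$proj <- pr$cache
    ca$fbn <- bno$cache
    ca$frelu <- rl$cache
  }
  cl1 <- fc_fwd(fused, p$cls1_W, p$cls1_b)
  bno <- bnc_fwd(cl1$y, p$clsbn_g, p$clsbn_b, bn$clsbn$rm, bn$clsbn$rv, training)
  bn$clsbn$rm <- bno$rm
  bn$clsbn$rv <- bno$rv
  rl <- relu_fwd(bno$y)
  h <- rl$y                       # penultimate feature (pre-dropout)
  dr <- dropout_fwd(h, cfg$dropout_cls, training)
  cl2 <- fc_fwd(dr$y, p$cls2_W, p$cls2_b)
  ca$cls1 <- cl1$cache
  ca$clsbn <- bno$cache
  ca$clsrelu <- rl$cache
  ca$clsdrop <- dr$cache
  ca$cls2 <- cl2$cache
  list(alpha = alpha, f_fused = fused, h = h, logits = cl2$y,
       cache = ca, bn = bn)
}

# dh_extra: additional gradient landing directly on h (center loss)
head_bwd <- function(dlogits, dh_extra, p, cache, cfg) {
  g <- list()
  fb <- fc_bwd(dlogits, cache$cls2)
  g$cls2_W <- fb$dW
  g$cls2_b <- fb$db
  dh <- dropout_bwd(fb$dx, cache$clsdrop)
  if (!is.null(dh_extra)) dh <- dh + dh_extra
  d <- relu_bwd(dh, cache$clsrelu)
  bb <- bnc_bwd(d, cache$clsbn)
  g$clsbn_g <- bb$dg
  g$clsbn_b <- bb$db
  fb <- fc_bwd(bb$dx, cache$cls1)
  g$cls1_W <- fb$dW
  g$cls1_b <- fb$db
  dfused <- fb$dx
  if (cfg$fusion == "single") {
    if (cfg$use_cnn) {
      return(list(grads = g, df_cnn = dfused, df_attn = NULL))
    }
    return(list(grads = g, df_cnn = NULL, df_attn = dfused))
  }
  d <- relu_bwd(dfused, cache$frelu)
  bb <- bnc_bwd(d, cache$fbn)
  g$fbn_g <- bb$dg
  g$fbn_b <- bb$db
  fb <- fc_bwd(bb$dx, cache$proj)
  g$fproj_W <- fb$dW
  g$fproj_b <- fb$db
  dwin <- fb$dx
  d128 <- cfg$d
  if (cfg$fusion == "gate") {
    gc <- cache$gate
    alpha <- gc$alpha
    dw_cnn <- dwin[, seq_len(d128), drop = FALSE]
    dw_attn <- dwin[, d128 + seq_len(d128), drop = FALSE]
    df_cnn <- dw_cnn * alpha
    df_attn <- dw_attn * (1 - alpha)
    dalpha <- rowSums(dw_cnn * gc$f_cnn) - rowSums(dw_attn * gc$f_attn)
    dz <- dalpha * alpha * (1 - alpha)
    fb <- fc_bwd(matrix(dz, ncol = 1L), gc$g2)
    g$gate2_W <- fb$dW
    g$gate2_b <- fb$db
    d <- relu_bwd(fb$dx, gc$g1r)
    fb <- fc_bwd(d, gc$g1)
    g$gate1_W <- fb$dW
    g$gate1_b <- fb$db
    dcat <- fb$dx
    df_cnn <- df_cnn + dcat[, seq_len(d128), drop = FALSE]
    df_attn <- df_attn + dcat[, d128 + seq_len(d128), drop = FALSE]
  } else {
    df_cnn <- dwin[, seq_len(d128), drop = FALSE]
    df_attn <- dwin[, d128 + seq_len(d128), drop = FALSE]
  }
  list(grads = g, df_cnn = df_cnn, df_attn = df_attn)
}

## ---- discriminators ---------------------------------------------------------

disc_fwd <- function(p, tag, f, cfg, training) {
  f1 <- fc_fwd(f, p[[paste0(tag, "_W1")]], p[[paste0(tag, "_b1")]])
  r1 <- relu_fwd(f1$y)
  d1 <- dropout_fwd(r1$y, cfg$dropout_disc, training)
  f2 <- fc_fwd(d1$y, p[[paste0(tag, "_W2")]], p[[paste0(tag, "_b2")]])
  r2 <- relu_fwd(f2$y)
  d2 <- dropout_fwd(r2$y, cfg$dropout_disc, training)
  f3 <- fc_fwd(d2$y, p[[paste0(tag, "_W3")]], p[[paste0(tag, "_b3")]])
  list(logit = f3$y[, 1L],
       cache = list(f1 = f1$cache, r1 = r1$cache, d1 = d1$cache,
                    f2 = f2$cache, r2 = r2$cache, d2 = d2$cache,
                    f3 = f3$cache, tag = tag))
}

disc_bwd <- function(dlogit, cache) {
  tag <- cache$tag
  g <- list()
  fb <- fc_bwd(matrix(dlogit, ncol = 1L), cache$f3)
  g[[paste0(tag, "_W3")]] <- fb$dW
  g[[paste0(tag, "_b3")]] <- fb$db
  d <- dropout_bwd(fb$dx, cache$d2)
  d <- relu_bwd(d, cache$r2)
  fb <- fc_bwd(d, cache$f2)
  g[[paste0(tag, "_W2")]] <- fb$dW
  g[[paste0(tag, "_b2")]] <- fb$db
  d <- dropout_bwd(fb$dx, cache$d1)
  d <- relu_bwd(d, cache$r1)
  fb <- fc_bwd(d, cache$f1)
  g[[paste0(tag, "_W1")]] <- fb$dW
  g[[paste0(tag, "_b1")]] <- fb$db
  list(grads = g, df = fb$dx)
}

## ---- whole-network forward --------------------------------------------------

# x: raw (already dataset-standardized) n x 10 x 120 array. Instance
# normalization is the network's first operation.
mgda_fwd <- function(p, bn, x, cfg, training = FALSE) {
  d <- dim(x)
  if (length(d) != 3L || d[2L] != C_SENSORS || d[3L] != T_STEPS) {
    stop("input batch must be n x ", C_SENSORS, " x ", T_STEPS,
         "; got ", paste(d, collapse = " x "))
  }
  xn <- instance_normalize_array(x)
  f_cnn <- NULL
  f_attn <- NULL
  ccache <- NULL
  acache <- NULL
  if (cfg$use_cnn) {
    cb <- cnn_branch_fwd(p, bn, xn, cfg, training)
    f_cnn <- cb$f
    ccache <- cb$cache
    bn <- cb$bn
  }
  if (cfg$use_attn) {
    ab <- attn_branch_fwd(p, bn, xn, cfg, training)
    f_attn <- ab$f
    acache <- ab$cache
    bn <- ab$bn
  }
  hd <- head_fwd(p, bn, f_cnn, f_attn, cfg, training)
  bn <- hd$bn
  list(f_cnn = f_cnn, f_attn = f_attn, alpha = hd$alpha,
       f_fused = hd$f_fused, h = hd$h, logits = hd$logits,
       cache = list(cnn = ccache, attn = acache, head = hd$cache),
       bn = bn)
}

# combine per-branch gradients (classifier path + optional adversarial extras)
# into parameter gradients
mgda_bwd <- function(fwd, dlogits, dh_extra, p, cfg,
                     df_cnn_extra = NULL, df_attn_extra = NULL) {
  hb <- head_bwd(dlogits, dh_extra, p, fwd$cache$head, cfg)
  g <- hb$grads
  if (cfg$use_cnn) {
    df <- hb$df_cnn
    if (is.null(df)) df <- matrix(0, nrow(fwd$f_cnn), cfg$d)
    if (!is.null(df_cnn_extra)) df <- df + df_cnn_extra
    g <- c(g, cnn_branch_bwd(df, fwd$cache$cnn))
  }
  if (cfg$use_attn) {
    df <- hb$df_attn
    if (is.null(df)) df <- matrix(0, nrow(fwd$f_attn), cfg$d)
    if (!is.null(df_attn_extra)) df <- df + df_attn_extra
    g <- c(g, attn_branch_bwd(df, p, fwd$cache$attn, cfg))
  }
  g
}
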