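# Adam with per-group learning rates and per-stage cosine annealing.

adam_init <- function(params, names_trainable) {
  list(
    m = lapply(params[names_trainable], function(x) x * 0),
    v = lapply(params[names_trainable], function(x) x * 0),
    t = 0L,
    names = names_trainable
  )
}

# lr_by_name: named numeric vector giving the (already annealed) learning
# rate for every trainable parameter
adam_step <- function(params, grads, state, lr_by_name,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in state$names) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr_by_name[[nm]] * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# cosine annealing factor for 0-based epoch e of E: starts at 1, decays to
# ~0 by the end of the stage
cosine_factor <- function(e, E) {
  0.5 * (1 + cos(pi * e / E))
}

# expand group learning rates to per-parameter rates
lr_map <- function(names_trainable, group_lrs, factor = 1) {
  lr <- vapply(names_trainable, function(nm) {
    grp <- param_group(nm)
    if (!grp %in% names(group_lrs)) 0 else group_lrs[[grp]]
  }, 0)
  lr * factor
}
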