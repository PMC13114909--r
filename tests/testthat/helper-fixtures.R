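# Shared fixture builders: everything is generated in code at test time.

# a small deterministic dataset with the given per-class/day layout
tiny_dataset <- function(n_classes = 3L, per_day = 2L, n_days = 5L,
                         seed = 42L, domain = "source", noise_sd = 0.02) {
  cfg <- sim_config(
    n_classes = n_classes, samples_per_class_per_day = per_day,
    n_days = n_days, noise_sd = noise_sd, seed = seed
  )
  generate_domain(cfg, domain = domain, id_prefix = paste0(domain, seed))
}

# noiseless single-exponential config with flat class structure, matching the
# closed-form kinetic law exactly
noiseless_config <- function(n_classes = 2L, A = 2, tau = 20, B = 1,
                             per_day = 1L, n_days = 1L) {
  sim_config(
    n_classes = n_classes, samples_per_class_per_day = per_day,
    n_days = n_days,
    baseline = rep(B, 10),
    class_patterns = matrix(A, n_classes, 10),
    class_tau_mult = matrix(1, n_classes, 10),
    class_transient = matrix(0, n_classes, 10),
    tau = rep(tau, 10),
    noise_sd = 0, day_gain_sd = 0, drift_slope_sd = 0, seed = 7L
  )
}

# the single-error confusion scenario: `per_class` test samples per class,
# one sample of true class `err_from` predicted as `err_to` (0-based)
single_error_labels <- function(n_classes, per_class, err_from, err_to) {
  y_true <- rep(seq_len(n_classes) - 1L, each = per_class)
  y_pred <- y_true
  flip <- which(y_true == err_from)[1L]
  y_pred[flip] <- err_to
  list(y_true = y_true, y_pred = y_pred)
}
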