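#' Synthetic E-nose simulator configuration
#'
#' The simulator emulates metal-oxide sensor kinetics during the 120-s
#' sampling stage: each channel rises from its baseline toward a class- and
#' sensor-specific steady state along a first-order exponential,
#' `r_s(t) = B_s + A_ks * (1 - exp(-t / tau_s))`, modulated by multiplicative
#' per-day session gains, a slow linear drift, and i.i.d. Gaussian noise.
#' Only the sampling stage is modeled; the cleaning/recovery phase is never
#' recorded by the acquisition protocol and is therefore not simulated.
#'
#' @param n_classes number of classes.
#' @param samples_per_class_per_day measurements acquired per class per day.
#' @param n_days number of acquisition days.
#' @param baseline length-10 per-sensor baseline conductance `B_s`.
#' @param class_patterns `n_classes x 10` steady-state amplitude matrix
#'   `A_ks`; defaults to a low-rank pattern family drawn from `seed`.
#' @param class_tau_mult `n_classes x 10` matrix of multiplicative rise-time
#'   modifiers: class `k` responds on sensor `s` with time constant
#'   `tau_s * class_tau_mult[k, s]`. Defaults to a low-rank log-scale family
#'   drawn from `seed`; setting it to all ones recovers purely
#'   amplitude-coded classes. Kinetic class signatures matter because the
#'   classifier's instance normalization removes per-channel offset and
#'   scale, so amplitude differences alone cannot separate classes.
#' @param tau length-10 rise time constants (time steps), strictly positive.
#' @param class_transient `n_classes x 10` matrix of transient-bump peak
#'   amplitudes (conductance units): each response carries an early
#'   class-specific overshoot `P_ks * (exp(-t/tau_dec) - exp(-t/tau_rise))`
#'   (peak-normalised), emulating the analyte-specific adsorption transients
#'   MOS arrays show before settling. This is the local temporal structure
#'   the CNN branch targets; set it to zeros for pure first-order kinetics.
#'   Defaults to a low-rank non-negative family drawn from `seed`.
#' @param transient_rise_frac,transient_decay_frac rise/decay time constants
#'   of the bump as fractions of each sensor's `tau`.
#' @param noise_sd sd of additive i.i.d. Gaussian observation noise.
#' @param day_gain_sd sd of the per-(day, channel) multiplicative session gain
#'   around 1 — the session effect that motivates day-wise splitting.
#' @param drift_slope_sd sd of the per-measurement linear drift slope.
#' @param seed integer seed governing pattern generation and sampling.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_classes = 12L,
                       samples_per_class_per_day = 10L,
                       n_days = 12L,
                       baseline = rep(1, 10),
                       class_patterns = NULL,
                       class_tau_mult = NULL,
                       tau = seq(10, 40, length.out = 10),
                       class_transient = NULL,
                       transient_rise_frac = 0.15,
                       transient_decay_frac = 0.6,
                       noise_sd = 0.02,
                       day_gain_sd = 0.05,
                       drift_slope_sd = 1e-4,
                       seed = 1L) {
  n_classes <- as.integer(n_classes)
  stopifnot(n_classes >= 1L, samples_per_class_per_day >= 1L, n_days >= 1L,
            length(baseline) == C_SENSORS, length(tau) == C_SENSORS,
            all(tau > 0), noise_sd >= 0, day_gain_sd >= 0, drift_slope_sd >= 0)
  if (is.null(class_patterns)) {
    class_patterns <- default_class_patterns(n_classes, seed)
  }
  class_patterns <- as.matrix(class_patterns)
  if (nrow(class_patterns) != n_classes || ncol(class_patterns) != C_SENSORS) {
    stop("class_patterns must be n_classes x ", C_SENSORS)
  }
  if (is.null(class_tau_mult)) {
    class_tau_mult <- default_class_tau_mult(n_classes, seed)
  }
  class_tau_mult <- as.matrix(class_tau_mult)
  if (nrow(class_tau_mult) != n_classes ||
      ncol(class_tau_mult) != C_SENSORS || any(class_tau_mult <= 0)) {
    stop("class_tau_mult must be a positive n_classes x ", C_SENSORS,
         " matrix")
  }
  if (is.null(class_transient)) {
    class_transient <- default_class_transient(n_classes, seed)
  }
  class_transient <- as.matrix(class_transient)
  if (nrow(class_transient) != n_classes ||
      ncol(class_transient) != C_SENSORS) {
    stop("class_transient must be n_classes x ", C_SENSORS)
  }
  stopifnot(transient_rise_frac > 0, transient_decay_frac > transient_rise_frac)
  structure(
    list(n_classes = n_classes,
         samples_per_class_per_day = as.integer(samples_per_class_per_day),
         n_days = as.integer(n_days),
         baseline = as.numeric(baseline),
         class_patterns = class_patterns,
         class_tau_mult = class_tau_mult,
         tau = as.numeric(tau),
         class_transient = class_transient,
         transient_rise_frac = transient_rise_frac,
         transient_decay_frac = transient_decay_frac,
         noise_sd = noise_sd, day_gain_sd = day_gain_sd,
         drift_slope_sd = drift_slope_sd,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Class steady-state amplitudes drawn from a rank-3 latent family: classes are
# points in a 3-D "aroma space" mapped through a shared positive loading
# matrix, so classes overlap realistically instead of being axis-aligned.
default_class_patterns <- function(n_classes, seed) {
  with_seed(derive_seed(seed, "patterns"), {
    latent <- matrix(rnorm(n_classes * 3), n_classes, 3)
    loading <- matrix(runif(3 * C_SENSORS, 0.2, 1), 3, C_SENSORS)
    A <- 1.5 + latent %*% loading * 0.6
    pmax(A, 0.1)
  })
}

# Per-class, per-sensor transient-bump peak amplitudes: rank-3 latent family,
# non-negative, roughly 0-1.2 in plateau units
default_class_transient <- function(n_classes, seed) {
  with_seed(derive_seed(seed, "transient"), {
    latent <- matrix(rnorm(n_classes * 3), n_classes, 3)
    loading <- matrix(runif(3 * C_SENSORS, 0.2, 1), 3, C_SENSORS)
    pmax(0.5 + latent %*% loading * 0.35, 0)
  })
}

# Per-class, per-sensor rise-time multipliers from a rank-3 log-scale latent
# family: each class responds with its own kinetic signature on each sensor
# (multipliers roughly in [0.6, 1.7]).
default_class_tau_mult <- function(n_classes, seed) {
  with_seed(derive_seed(seed, "tau_mult"), {
    latent <- matrix(rnorm(n_classes * 3), n_classes, 3)
    loading <- matrix(runif(3 * C_SENSORS, 0.3, 1), 3, C_SENSORS)
    exp(pmin(pmax(latent %*% loading * 0.3, -0.7), 0.8))
  })
}

#' Source-to-target domain shift
#'
#' Parameterises how a target domain's sensing conditions differ from the
#' source's: per-channel multiplicative gain and additive offset (sensor
#' response and baseline drift between campaigns), a global rise-time scale
#' (altered headspace dynamics), and Gaussian perturbation of the class
#' steady-state patterns (different sample chemistry). The identity shift is
#' gain 1, offset 0, tau_scale 1, perturb_sd 0.
#'
#' @param channel_gain length-10 multiplicative gain.
#' @param channel_offset length-10 additive offset.
#' @param tau_scale positive scale on all rise time constants.
#' @param pattern_perturb_sd sd of the one-off Gaussian perturbation applied
#'   to the class-pattern matrix when a domain is generated.
#' @param tau_perturb_sd log-scale sd of the one-off perturbation applied to
#'   the class rise-time multipliers (kinetic component of the shift).
#' @return an object of class `domain_shift`.
#' @export
domain_shift <- function(channel_gain = rep(1, 10),
                         channel_offset = rep(0, 10),
                         tau_scale = 1,
                         pattern_perturb_sd = 0,
                         tau_perturb_sd = 0) {
  stopifnot(length(channel_gain) == C_SENSORS,
            length(channel_offset) == C_SENSORS,
            tau_scale > 0, pattern_perturb_sd >= 0, tau_perturb_sd >= 0)
  structure(
    list(channel_gain = as.numeric(channel_gain),
         channel_offset = as.numeric(channel_offset),
         tau_scale = tau_scale,
         pattern_perturb_sd = pattern_perturb_sd,
         tau_perturb_sd = tau_perturb_sd),
    class = "domain_shift"
  )
}

#' Is a shift the identity?
#' @param shift a [domain_shift()].
#' @return `TRUE` iff gain = 1, offset = 0, tau_scale = 1 and both
#'   perturbation sds are 0.
#' @export
is_identity_shift <- function(shift) {
  all(shift$channel_gain == 1) && all(shift$channel_offset == 0) &&
    shift$tau_scale == 1 && shift$pattern_perturb_sd == 0 &&
    shift$tau_perturb_sd == 0
}

# Closed-form noiseless kinetic curve for one channel: B + A(1 - exp(-t/tau)),
# t = 0 .. T-1 (0-based sampling steps).
kinetic_curve <- function(B, A, tau, t = 0:(T_STEPS - 1L)) {
  B + A * (1 - exp(-t / tau))
}

#' Simulate one E-nose measurement
#'
#' Channel `s` at 0-based time `t` follows
#' `g_day[s] * gain[s] * (B_s + A'_ks (1 - exp(-t / (tau_s * tau_scale)))) +
#' offset[s] + drift * t + noise`, where `A'` is the (possibly perturbed)
#' class-pattern matrix, `g_day` the day's session gain and `noise` i.i.d.
#' Gaussian. Randomness is drawn from the current R RNG stream so callers
#' control reproducibility.
#'
#' @param cfg a [sim_config()].
#' @param shift a [domain_shift()].
#' @param class_k 0-based class index.
#' @param day 1-based day index.
#' @param sample_id identifier for the measurement.
#' @param day_gain optional length-10 session gain for this day (drawn fresh
#'   if omitted; [generate_domain()] draws one per day).
#' @param patterns optional pre-perturbed class-pattern matrix.
#' @param tau_mult optional pre-perturbed class rise-time multiplier matrix.
#' @param transient optional pre-perturbed transient-amplitude matrix.
#' @param domain `"source"` or `"target"` tag for the output.
#' @return an [enose_measurement()].
#' @export
simulate_measurement <- function(cfg, shift = domain_shift(), class_k, day,
                                 sample_id = "sim", day_gain = NULL,
                                 patterns = NULL, tau_mult = NULL,
                                 transient = NULL, domain = "source") {
  if (class_k < 0L || class_k >= cfg$n_classes) {
    stop("class_k must lie in [0, n_classes); got ", class_k)
  }
  if (day < 1L || day > cfg$n_days) {
    stop("day must lie in [1, n_days]; got ", day)
  }
  if (is.null(patterns)) {
    patterns <- perturb_patterns(cfg, shift)
  }
  if (is.null(tau_mult)) {
    tau_mult <- perturb_tau_mult(cfg, shift)
  }
  if (is.null(transient)) {
    transient <- perturb_transient(cfg, shift)
  }
  if (is.null(day_gain)) {
    day_gain <- 1 + rnorm(C_SENSORS, 0, cfg$day_gain_sd)
  }
  t <- 0:(T_STEPS - 1L)
  tau_eff <- cfg$tau * tau_mult[class_k + 1L, ] * shift$tau_scale
  rise <- 1 - exp(-outer(1 / tau_eff, t))               # C x T
  v <- cfg$baseline + patterns[class_k + 1L, ] * rise   # C x T, column recycling
  P <- transient[class_k + 1L, ]
  if (any(P != 0)) {
    v <- v + P * transient_bump(tau_eff, cfg$transient_rise_frac,
                                cfg$transient_decay_frac, t)
  }
  v <- v * (day_gain * shift$channel_gain) + shift$channel_offset
  drift <- rnorm(1, 0, cfg$drift_slope_sd)
  v <- v + matrix(drift * t, C_SENSORS, T_STEPS, byrow = TRUE)
  if (cfg$noise_sd > 0) {
    v <- v + matrix(rnorm(C_SENSORS * T_STEPS, 0, cfg$noise_sd),
                    C_SENSORS, T_STEPS)
  }
  enose_measurement(v, sample_id, class_k, domain = domain, day = day)
}

# One-off Gaussian perturbation of the class patterns under a shift; uses the
# current RNG stream.
perturb_patterns <- function(cfg, shift) {
  A <- cfg$class_patterns
  if (shift$pattern_perturb_sd > 0) {
    A <- A + matrix(rnorm(length(A), 0, shift$pattern_perturb_sd), nrow(A))
    A <- pmax(A, 0.05)
  }
  A
}

# one-off Gaussian perturbation of the transient amplitudes (same sd as the
# steady-state patterns, scaled to the smaller transient magnitude)
perturb_transient <- function(cfg, shift) {
  P <- cfg$class_transient
  if (shift$pattern_perturb_sd > 0) {
    P <- P + matrix(rnorm(length(P), 0, 0.5 * shift$pattern_perturb_sd),
                    nrow(P))
    P <- pmax(P, 0)
  }
  P
}

# Peak-normalised double-exponential transient per sensor: rises with time
# constant rf * tau, decays with df * tau, maximum 1.
transient_bump <- function(tau_eff, rf, df, t) {
  tr <- rf * tau_eff
  td <- df * tau_eff
  bump <- exp(-outer(1 / td, t)) - exp(-outer(1 / tr, t))  # C x T
  # analytic peak of e^{-t/td} - e^{-t/tr}
  tstar <- log(td / tr) / (1 / tr - 1 / td)
  peak <- exp(-tstar / td) - exp(-tstar / tr)
  bump / peak
}

# one-off log-normal perturbation of the class rise-time multipliers
perturb_tau_mult <- function(cfg, shift) {
  M <- cfg$class_tau_mult
  if (shift$tau_perturb_sd > 0) {
    M <- M * exp(matrix(rnorm(length(M), 0, shift$tau_perturb_sd), nrow(M)))
  }
  M
}

#' Generate a full simulated domain
#'
#' Produces `n_classes * samples_per_class_per_day * n_days` measurements,
#' balanced per class per day, deterministically from `cfg$seed`: the pattern
#' perturbation is drawn once per domain, the session gain once per day, and
#' noise/drift per measurement.
#'
#' @param cfg a [sim_config()].
#' @param shift a [domain_shift()].
#' @param domain `"source"` or `"target"` tag.
#' @param id_prefix prefix for generated sample ids.
#' @return an [enose_dataset()].
#' @export
generate_domain <- function(cfg, shift = domain_shift(), domain = "source",
                            id_prefix = domain) {
  n <- cfg$n_classes * cfg$samples_per_class_per_day * cfg$n_days
  with_seed(derive_seed(cfg$seed, paste0("domain_", id_prefix)), {
    patterns <- perturb_patterns(cfg, shift)
    tau_mult <- perturb_tau_mult(cfg, shift)
    transient <- perturb_transient(cfg, shift)
    x <- array(0, c(n, C_SENSORS, T_STEPS))
    ids <- character(n)
    labels <- integer(n)
    days <- integer(n)
    i <- 0L
    for (day in seq_len(cfg$n_days)) {
      day_gain <- 1 + rnorm(C_SENSORS, 0, cfg$day_gain_sd)
      for (k in seq_len(cfg$n_classes) - 1L) {
        for (r in seq_len(cfg$samples_per_class_per_day)) {
          i <- i + 1L
          m <- simulate_measurement(
            cfg, shift, class_k = k, day = day,
            sample_id = sprintf("%s_d%02d_c%02d_r%02d", id_prefix, day, k, r),
            day_gain = day_gain, patterns = patterns, tau_mult = tau_mult,
            transient = transient, domain = domain
          )
          x[i, , ] <- m$values
          ids[i] <- m$sample_id
          labels[i] <- k
          days[i] <- day
        }
      }
    }
    enose_dataset(x, ids, labels, domain = domain, day = days,
                  n_classes = cfg$n_classes)
  })
}

#' Paper-scale simulator presets
#'
#' `sim_preset_source()` mirrors a 12-class source campaign (10 measurements
#' per class per day over 12 days, 1440 in total); `sim_preset_target1()` a
#' 6-class target (6 per class per day over 10 days, 360) and
#' `sim_preset_target2()` an 8-class target (480).
#'
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
sim_preset_source <- function(seed = 1L) {
  sim_config(n_classes = 12L, samples_per_class_per_day = 10L, n_days = 12L,
             seed = seed)
}

#' @rdname sim_preset_source
#' @export
sim_preset_target1 <- function(seed = 1L) {
  sim_config(n_classes = 6L, samples_per_class_per_day = 6L, n_days = 10L,
             seed = seed)
}

#' @rdname sim_preset_source
#' @export
sim_preset_target2 <- function(seed = 1L) {
  sim_config(n_classes = 8L, samples_per_class_per_day = 6L, n_days = 10L,
             seed = seed)
}

#' Build a source-to-target transfer benchmark
#'
#' The source domain is a 12-class campaign; the target is a 6-class campaign
#' whose steady-state patterns are pairwise blends of the source classes (so
#' the two label spaces are related but not identical, as in cross-category
#' transfer), observed under a [domain_shift()] whose magnitude scales with
#' `difficulty`: at 0 the shift is the identity, at 1 the channel gains/offsets,
#' rise-time scale and pattern perturbation reach their calibrated maxima.
#'
#' @param seed integer seed.
#' @param difficulty shift magnitude in `[0, 1]`.
#' @param source_samples_per_day,source_days,target_samples_per_day,target_days
#'   campaign sizes; the defaults are the full-scale campaign presets
#'   (source 12 x 10 x 12 = 1440, target 6 x 6 x 10 = 360) and can be reduced
#'   for cheap experimentation without changing the generating process.
#' @return list with `source` and `target` datasets plus the configs used.
#' @export
make_transfer_benchmark <- function(seed = 1L, difficulty = 0.5,
                                    source_samples_per_day = 10L,
                                    source_days = 12L,
                                    target_samples_per_day = 6L,
                                    target_days = 10L) {
  stopifnot(difficulty >= 0, difficulty <= 1)
  source_cfg <- sim_config(
    n_classes = 12L, samples_per_class_per_day = source_samples_per_day,
    n_days = source_days, seed = seed
  )
  # target classes: blends of consecutive source class pairs — arithmetic in
  # amplitude space, geometric in rise-time space
  src_patterns <- source_cfg$class_patterns
  src_tau_mult <- source_cfg$class_tau_mult
  src_transient <- source_cfg$class_transient
  n_target_classes <- 6L
  blend <- matrix(0, n_target_classes, C_SENSORS)
  blend_tau <- matrix(0, n_target_classes, C_SENSORS)
  blend_tr <- matrix(0, n_target_classes, C_SENSORS)
  for (k in seq_len(n_target_classes)) {
    blend[k, ] <- 0.6 * src_patterns[2L * k - 1L, ] + 0.4 * src_patterns[2L * k, ]
    blend_tau[k, ] <- src_tau_mult[2L * k - 1L, ]^0.6 * src_tau_mult[2L * k, ]^0.4
    blend_tr[k, ] <- 0.6 * src_transient[2L * k - 1L, ] +
      0.4 * src_transient[2L * k, ]
  }
  target_cfg <- sim_config(
    n_classes = n_target_classes,
    samples_per_class_per_day = target_samples_per_day,
    n_days = target_days, class_patterns = blend,
    class_tau_mult = blend_tau,
    class_transient = blend_tr,
    tau = source_cfg$tau, baseline = source_cfg$baseline,
    noise_sd = source_cfg$noise_sd, day_gain_sd = source_cfg$day_gain_sd,
    drift_slope_sd = source_cfg$drift_slope_sd,
    seed = derive_seed(seed, "target")
  )
  shift <- with_seed(derive_seed(seed, "shift"), {
    domain_shift(
      channel_gain = 1 + difficulty * rnorm(C_SENSORS, 0, 0.25),
      channel_offset = difficulty * rnorm(C_SENSORS, 0, 0.3),
      tau_scale = 1 + 0.5 * difficulty,
      pattern_perturb_sd = 0.35 * difficulty,
      tau_perturb_sd = 0.15 * difficulty
    )
  })
  if (difficulty == 0) shift <- domain_shift()
  list(
    source = generate_domain(source_cfg, domain_shift(), domain = "source"),
    target = generate_domain(target_cfg, shift, domain = "target"),
    source_cfg = source_cfg, target_cfg = target_cfg, shift = shift
  )
}
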