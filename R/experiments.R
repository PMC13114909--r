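# Experiment drivers: multi-variant ablation sweeps, label-efficiency
# curves, and stage-wise domain-discrepancy (MMD) measurement, all on a
# source/target benchmark with a day-wise target split.

ALL_VARIANTS <- c("full", "cnn_only", "attn_only", "concat_fusion", "no_da",
                  "local_only_da", "global_only_da", "no_finetune")

# one checkpoint cache per seed, nested inside a caller-supplied environment
# when experiment drivers share fits
seed_cache <- function(outer, seed) {
  if (is.null(outer)) return(new.env(parent = emptyenv()))
  key <- paste0("seed_", seed)
  if (is.null(outer[[key]])) outer[[key]] <- new.env(parent = emptyenv())
  outer[[key]]
}

#' Run the ablation sweep
#'
#' Fits the full model and the seven single-component ablation variants on a
#' source/target benchmark for each seed, evaluating every fit on the
#' day-wise held-out target test days. Stage-1 and Stage-2 checkpoints are
#' shared between variants that use identical settings for those stages, so
#' e.g. `no_finetune` reuses the full model's alignment.
#'
#' @param benchmark a list with `source` and `target` datasets, as returned
#'   by [make_transfer_benchmark()].
#' @param seeds integer vector of training seeds.
#' @param epochs named `c(pretrain=, align=, finetune=)` epochs.
#' @param variants subset of the eight variants (default: all).
#' @param split a [split_spec()] for the target day-wise split.
#' @param batch_size mini-batch size.
#' @param losses a [loss_config()].
#' @param verbose print progress.
#' @param .cache optional environment holding per-seed checkpoint caches so
#'   several experiment drivers can share Stage-1/2 fits.
#' @return an object of class `ablation_result`: `runs` (per seed x variant
#'   metrics data.frame), `summary` (mean and sd per variant), `seeds`.
#' @export
run_ablation <- function(benchmark, seeds = 1:3,
                         epochs = c(pretrain = 200L, align = 200L,
                                    finetune = 300L),
                         variants = ALL_VARIANTS,
                         split = split_spec(1:8, 9:10),
                         batch_size = 32L, losses = loss_config(),
                         verbose = FALSE, .cache = NULL) {
  bad <- setdiff(variants, ALL_VARIANTS)
  if (length(bad)) stop("unknown variant(s): ", paste(bad, collapse = ", "))
  tsplit <- day_wise_split(benchmark$target, split)
  if (is.null(tsplit$test)) stop("benchmark split has no test days")
  runs <- NULL
  models_last <- list()
  for (seed in seeds) {
    cache <- seed_cache(.cache, seed)
    for (variant in variants) {
      if (verbose) message("seed ", seed, " variant ", variant)
      fit <- mgda_net(benchmark$source, tsplit$train,
                      target_test = tsplit$test, variant = variant,
                      epochs = epochs, batch_size = batch_size, seed = seed,
                      losses = losses, .cache = cache)
      m <- fit$test_metrics
      runs <- rbind(runs, data.frame(
        variant = variant, seed = seed,
        accuracy = m$overall_accuracy, f1_macro = m$f1_macro,
        kappa = m$kappa, precision_macro = m$precision_macro,
        recall_macro = m$recall_macro
      ))
      if (seed == seeds[[length(seeds)]]) models_last[[variant]] <- fit
    }
  }
  metrics <- c("accuracy", "f1_macro", "kappa", "precision_macro",
               "recall_macro")
  summ <- do.call(rbind, lapply(split(runs, runs$variant), function(d) {
    out <- data.frame(variant = d$variant[1], n_seeds = nrow(d))
    for (m in metrics) {
      out[[paste0(m, "_mean")]] <- mean(d[[m]])
      out[[paste0(m, "_sd")]] <- if (nrow(d) > 1) sd(d[[m]]) else NA_real_
    }
    out
  }))
  summ <- summ[order(match(summ$variant, ALL_VARIANTS)), ]
  rownames(summ) <- NULL
  structure(
    list(runs = runs, summary = summ, seeds = seeds, epochs = epochs,
         models_last_seed = models_last,
         test_ids = tsplit$test$sample_id),
    class = "ablation_result"
  )
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("<ablation_result> ", length(x$seeds), " seed(s)\n", sep = "")
  print(x$summary[, c("variant", "accuracy_mean", "accuracy_sd", "f1_macro_mean",
                      "kappa_mean")], digits = 4, row.names = FALSE)
  invisible(x)
}

#' Label-efficiency experiment
#'
#' Keeps the Stage-1 and Stage-2 models fixed and repeats Stage 3 with the
#' labeled target training set stratified-subsampled at each ratio,
#' evaluating every fit on the unchanged day-wise test split.
#'
#' @param benchmark a list with `source` and `target` datasets.
#' @param ratios subsampling ratios in `(0, 1]`.
#' @param seeds integer training seeds (each rerandomises subsampling and
#'   Stage-3 training).
#' @param epochs named `c(pretrain=, align=, finetune=)` epochs.
#' @param split a [split_spec()] for the target day-wise split.
#' @param batch_size mini-batch size.
#' @param losses a [loss_config()].
#' @param verbose print progress.
#' @param .cache optional environment shared with [run_ablation()]: the
#'   protocol keeps Stage 1/2 fixed, so the full model's checkpoints are
#'   reused when the same seeds and epochs are supplied.
#' @return an object of class `label_efficiency_result`: `runs`, `summary`
#'   (mean/sd accuracy, f1, kappa and the labeled counts per ratio).
#' @export
run_label_efficiency <- function(benchmark, ratios = c(1, 0.8, 0.6, 0.4, 0.2),
                                 seeds = 1:3,
                                 epochs = c(pretrain = 200L, align = 200L,
                                            finetune = 300L),
                                 split = split_spec(1:8, 9:10),
                                 batch_size = 32L, losses = loss_config(),
                                 verbose = FALSE, .cache = NULL) {
  stopifnot(all(ratios > 0), all(ratios <= 1))
  tsplit <- day_wise_split(benchmark$target, split)
  if (is.null(tsplit$test)) stop("benchmark split has no test days")
  runs <- NULL
  for (seed in seeds) {
    cache <- seed_cache(.cache, seed)
    for (ratio in ratios) {
      if (verbose) message("seed ", seed, " ratio ", ratio)
      labeled <- stratified_subsample(tsplit$train, ratio,
                                      derive_seed(seed, paste0("ratio", ratio)))
      fit <- mgda_net(benchmark$source, tsplit$train,
                      target_test = tsplit$test, variant = "full",
                      epochs = epochs, batch_size = batch_size, seed = seed,
                      losses = losses, finetune_train = labeled,
                      .cache = cache)
      m <- fit$test_metrics
      runs <- rbind(runs, data.frame(
        ratio = ratio, seed = seed, labeled = length(labeled),
        accuracy = m$overall_accuracy, f1_macro = m$f1_macro, kappa = m$kappa
      ))
    }
  }
  summ <- do.call(rbind, lapply(split(runs, runs$ratio), function(d) {
    data.frame(
      ratio = d$ratio[1], labeled = d$labeled[1], n_seeds = nrow(d),
      accuracy_mean = mean(d$accuracy),
      accuracy_sd = if (nrow(d) > 1) sd(d$accuracy) else NA_real_,
      f1_macro_mean = mean(d$f1_macro),
      kappa_mean = mean(d$kappa)
    )
  }))
  summ <- summ[order(-summ$ratio), ]
  rownames(summ) <- NULL
  structure(
    list(runs = runs, summary = summ, seeds = seeds, ratios = ratios),
    class = "label_efficiency_result"
  )
}

#' @export
print.label_efficiency_result <- function(x, ...) {
  cat("<label_efficiency_result> ", length(x$seeds), " seed(s)\n", sep = "")
  print(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Domain discrepancy before and after adversarial alignment
#'
#' Computes the combined multi-kernel MMD between source and target-training
#' features at the requested tap points, using the Stage-1 checkpoint
#' (before alignment) and the Stage-2 checkpoint (after alignment) of a
#' fitted model.
#'
#' @param model a fitted [mgda_net()] whose variant ran Stage 2.
#' @param source,target_train the datasets the model was fitted on.
#' @param levels tap points to measure.
#' @return a data.frame with columns `level`, `stage`, `combined_mmd2`.
#' @export
mmd_by_stage <- function(model, source, target_train,
                         levels = c("local", "global", "fused")) {
  if (is.null(model$checkpoints$stage2)) {
    stop("model has no Stage-2 checkpoint; fit with a variant that aligns")
  }
  out <- NULL
  for (stage in c("stage1", "stage2")) {
    for (level in levels) {
      fs <- extract_level_features(model, source, level, stage)
      ft <- extract_level_features(model, target_train, level, stage)
      rep <- multikernel_mmd(fs, ft)
      out <- rbind(out, data.frame(
        level = level,
        stage = if (stage == "stage1") "after_stage1" else "after_stage2",
        combined_mmd2 = rep$combined
      ))
    }
  }
  out
}

#' Desk-scale experiment configuration
#'
#' The reduced problem size used by the package's end-to-end experiment
#' suite: a 12-class source campaign (2 measurements per class per day over
#' 6 days, 144 samples) transferred to a 6-class target campaign (3 per
#' class per day over 10 days, 180 samples; days 1-8 train, 9-10 test),
#' moderate-to-strong domain shift (`difficulty` 0.8), shortened stage
#' schedules (12/6/16 epochs) and 3 seeds. These sizes trade statistical
#' resolution for runtime so the full three-stage protocol, all eight
#' ablation variants and the label-efficiency sweep complete on a single
#' CPU core in minutes; the full-scale presets ([sim_preset_source()] and
#' friends, 200/200/300 epochs) remain the defaults everywhere else.
#'
#' @param seed benchmark seed (controls patterns, shift and sampling).
#' @return a list with `benchmark`, `epochs`, `seeds`, `split`,
#'   `difficulty`.
#' @export
desk_experiment_config <- function(seed = 11L) {
  difficulty <- 0.8
  list(
    benchmark = make_transfer_benchmark(
      seed = seed, difficulty = difficulty,
      source_samples_per_day = 2L, source_days = 6L,
      target_samples_per_day = 3L, target_days = 10L
    ),
    epochs = c(pretrain = 12L, align = 6L, finetune = 16L),
    seeds = 1:3,
    split = split_spec(1:8, 9:10),
    difficulty = difficulty
  )
}
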