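# Group statistics for repeated-measures designs, and the end-to-end
# experiment driver.

#' Within-subject standard error of the mean
#'
#' Each subject's row is centered on the grand mean (removing per-subject
#' offsets) before computing the per-condition standard error, giving error
#' bars appropriate for repeated-measures comparisons.
#'
#' @param values `subjects x conditions` matrix.
#' @return named numeric vector of per-condition SEs.
#' @export
within_subject_se <- function(values) {
  stopifnot(is.matrix(values), nrow(values) >= 2, ncol(values) >= 2)
  centered <- values - rowMeans(values) + mean(values)
  apply(centered, 2, sd) / sqrt(nrow(values))
}

#' Paired t test
#'
#' Standard paired t statistic with two-tailed p, `df = n - 1`. Zero-variance
#' differences are flagged as degenerate (p of 0 or 1 by the sign of the
#' constant difference).
#'
#' @param a,b equal-length paired samples (n >= 2).
#' @return list with `t`, `df`, `p`, `degenerate`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, df = length(d) - 1L, p = 1,
                                 degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1L, p = 0,
                degenerate = TRUE))
  }
  tt <- t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Default desk-scale experiment configuration
#'
#' @param seed master seed; all stage seeds derive from it.
#' @return named list accepted by [run_experiment()].
#' @export
default_experiment_config <- function(seed = 1) {
  list(
    seed = seed,
    lexicon = list(n_words = 30, n_phonemes = 16, length_range = c(3, 6),
                   neighborhood_density = 0.6, n_talkers = 3),
    coding = list(kind = "localist"),
    model = list(layer_sizes = 48, loss = "bce", c = 1, lr = 2e-3),
    training = list(n_epochs = 40, batch_size = 4, segments_per_stream = 2,
                    segment_frames = 600, snr_db = 20),
    linking = list(grouping = "layer", K = NULL),
    simulation = list(n_subjects = 4, n_channels = 6, snr_db = 10,
                      mixing = 1, stream_frames = 6000),
    mtrf = list(n_folds = 4, delta = 0.005)
  )
}

#' Run an end-to-end experiment
#'
#' Executes the full chain at the scale given by `config`: lexicon and token
#' synthesis, token partition, training stream construction, LSTM training,
#' evaluation (word error rate, competition profile), linking predictors,
#' auditory baseline predictors, simulated multi-subject responses with the
#' RNN contribution mixed in, encoding-model comparison, and paired group
#' statistics. Fully deterministic given `config` (one master seed derives all
#' stage seeds). When `out_dir` is given, results are cached there: re-running
#' with an identical configuration reloads the cached bundle.
#'
#' @param config list as from [default_experiment_config()].
#' @param out_dir optional cache/output directory.
#' @param verbose print stage progress.
#' @return list with `wer`, `wer_by_talker`, `competition`, `predictors`,
#'   `comparison` (per-subject ROI-mean improvements), `stats` (paired t and
#'   within-subject SEs), plus the `config`.
#' @export
run_experiment <- function(config = default_experiment_config(),
                           out_dir = NULL, verbose = FALSE) {
  if (!is.null(out_dir)) {
    cache <- file.path(out_dir, "experiment.rds")
    if (file.exists(cache)) {
      prev <- readRDS(cache)
      if (identical(prev$config, config)) {
        if (verbose) message("configuration unchanged; returning cached run")
        return(prev)
      }
    }
  }
  seed <- config$seed
  say <- function(...) if (verbose) message(...)

  say("stage 1/6: lexicon and tokens")
  lex <- do.call(build_lexicon,
                 c(config$lexicon, list(seed = derive_seed(seed, 1L))))
  tokens <- synthesize_tokens(lex, seed = derive_seed(seed, 2L))
  part <- partition_tokens(tokens, holdout_fraction = 1 / 16,
                           seed = derive_seed(seed, 3L))

  say("stage 2/6: model training")
  coding <- do.call(make_coding,
                    c(config$coding, list(n_words = length(lex$words),
                                          seed = derive_seed(seed, 4L))))
  cfg <- model_config(config$model$layer_sizes, coding,
                      loss = config$model$loss, c = config$model$c,
                      lr = config$model$lr)
  model <- build_model(cfg, seed = derive_seed(seed, 5L))
  src <- make_stream_source(tokens, coding, allowed = part$train,
                            batch_size = config$training$batch_size,
                            segments_per_stream =
                              config$training$segments_per_stream,
                            segment_frames = config$training$segment_frames,
                            snr_db = config$training$snr_db,
                            lill_c = if (cfg$loss == "lill") cfg$c else 1)
  model <- train_model(model, src, n_epochs = config$training$n_epochs,
                       seed = derive_seed(seed, 6L))

  say("stage 3/6: evaluation")
  eval_stream <- build_eval_stream(tokens, part, seed = derive_seed(seed, 7L))
  run <- run_model(model, eval_stream)
  act <- to_activation(run$outputs, coding)
  train_ann <- eval_stream$annotations[eval_stream$annotations$train, ]
  wer <- word_error_rate(act, train_ann)
  wer_tk <- word_error_rate(act, train_ann, by_talker = TRUE)
  comp <- competition_profile(act, train_ann, lex)

  say("stage 4/6: linking predictors")
  grouping <- if (identical(config$linking$grouping, "kmeans"))
    kmeans_grouping(run$hidden, config$linking$K,
                    seed = derive_seed(seed, 8L))
  else layer_grouping(run$hidden)
  Tn <- config$simulation$stream_frames
  stim <- build_training_stream(tokens, Tn, seed = derive_seed(seed, 9L),
                                allowed = part$train)
  stim_run <- run_model(model, stim)
  rnn_pred <- build_predictor_set(stim_run$hidden, grouping)

  say("stage 5/6: responses and encoding models")
  base_pred <- make_baseline_predictors(stim)
  T2 <- min(ncol(base_pred$x), ncol(rnn_pred$x))
  xb <- base_pred$x[, seq_len(T2), drop = FALSE]
  xr <- rnn_pred$x[, seq_len(T2), drop = FALSE]
  sim <- make_rnn_ground_truth(xb, xr, mixing = config$simulation$mixing,
                               n_subjects = config$simulation$n_subjects,
                               n_channels = config$simulation$n_channels,
                               snr_db = config$simulation$snr_db,
                               seed = derive_seed(seed, 10L))
  per_subject <- lapply(sim$subjects, function(s)
    model_comparison(xb, xr, s$response[sim$roi, , drop = FALSE],
                     n_folds = config$mtrf$n_folds,
                     delta = config$mtrf$delta))
  imp <- t(vapply(per_subject, function(m)
    c(base = mean(m$ve_base), full = mean(m$ve_full),
      raw = mean(m$improvement_raw)), numeric(3)))

  say("stage 6/6: group statistics")
  stats <- list(
    paired = paired_t(imp[, "full"], imp[, "base"]),
    within_se = within_subject_se(imp[, c("base", "full")]))

  result <- list(config = config, wer = wer, wer_by_talker = wer_tk,
                 competition = comp, history = model$history,
                 improvements = imp, stats = stats)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(result, file.path(out_dir, "experiment.rds"))
  }
  result
}
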