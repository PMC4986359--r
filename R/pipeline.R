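#' Full experiment configuration
#'
#' Cross-validated bundle of every stage's settings for a reproducible
#' end-to-end run: synthetic session generation, windowing, feature
#' pathway, classifier, synergy extraction and online simulation.
#' Everything random derives from `synth$seed`.
#'
#' @param synth a [synth_config()].
#' @param separation class-separation of the planted synergy codes,
#'   passed to [make_ground_truth()].
#' @param spec a [window_spec()].
#' @param pathway `"emg"` (per-channel MAV + VAR) or `"synergy"`
#'   (NMF synergy activations).
#' @param hidden_grid candidate hidden-layer sizes; a single value
#'   skips cross-validation.
#' @param lambda ELM ridge parameter.
#' @param cv_folds folds for hidden-size selection.
#' @param synergy_k fixed synergy count, or `NULL` for automatic
#'   selection by the explained-variance criteria.
#' @param variance_threshold,slope_threshold synergy-count criteria.
#' @param online an [online_config()].
#' @param offline_split fraction of training trials (split whole, per
#'   class) whose windows fit the decoder for the offline evaluation;
#'   the remaining trials form its held-out test set.
#' @param training_filter envelope mode used on training data
#'   (`"offline"` zero-phase by default; `"causal"` mirrors the online
#'   filtering exactly).
#' @param out_dir optional directory for artifacts (models, window
#'   features, trial logs, report); `NULL` writes nothing.
#' @return A `run_config` list.
#' @export
run_config <- function(synth = synth_config(), separation = 4,
                       spec = window_spec(),
                       pathway = c("emg", "synergy"),
                       hidden_grid = c(500L, 1000L, 2000L, 3500L, 5000L),
                       lambda = 1e-3, cv_folds = 2L,
                       synergy_k = NULL, variance_threshold = 0.90,
                       slope_threshold = 0.05,
                       online = online_config(spec = spec),
                       offline_split = 0.5,
                       training_filter = c("offline", "causal"),
                       out_dir = NULL) {
  pathway <- match.arg(pathway)
  training_filter <- match.arg(training_filter)
  stopifnot(inherits(synth, "synth_config"), inherits(spec, "window_spec"),
            inherits(online, "online_config"))
  if (spec$window > round(synth$trial_duration * synth$sample_rate))
    stop_input("window longer than a trial")
  if (offline_split <= 0 || offline_split >= 1)
    stop_input("offline_split must be in (0, 1)")
  structure(list(synth = synth, separation = separation, spec = spec,
                 pathway = pathway, hidden_grid = as.integer(hidden_grid),
                 lambda = lambda, cv_folds = as.integer(cv_folds),
                 synergy_k = synergy_k,
                 variance_threshold = variance_threshold,
                 slope_threshold = slope_threshold,
                 online = online, offline_split = offline_split,
                 training_filter = training_filter, out_dir = out_dir),
            class = "run_config")
}

# Stratified train/test split by class label. Used at the trial level:
# sliding windows overlap by 90 %, so windows from one trial share most
# of their samples and must land on the same side of the split to keep
# the held-out set independent.
stratified_split <- function(labels, fraction, seed) {
  with_seed(seed, {
    train <- logical(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n_tr <- max(1L, round(fraction * length(idx)))
      train[sample(idx, n_tr)] <- TRUE
    }
    train
  })
}

subset_features <- function(fm, keep) {
  fm$values <- fm$values[, keep, drop = FALSE]
  fm$labels <- fm$labels[keep]
  fm$trial <- fm$trial[keep]
  fm$window_end <- fm$window_end[keep]
  fm
}

#' Run one decoding experiment end to end
#'
#' Generates a training and a testing session from the planted synergy
#' ground truth, trains the configured feature pathway and the ELM
#' decoder, evaluates offline accuracy on a stratified held-out split
#' of the training windows, simulates the online testing phase, and
#' compiles every performance metric. Fully reproducible: the same
#' config (including its seed) produces the identical report.
#'
#' @param config a [run_config()].
#' @param truth optional pre-built [make_ground_truth()]; generated
#'   from the config otherwise.
#' @return An `experiment_result` list: `offline` (accuracy, confusion
#'   matrix, chosen hidden size, CV table), `online` (a
#'   [online_report()] `performance_report`), `variability` (per motion
#'   class, from the testing-phase envelope traces), `feature_dim`,
#'   `chosen_k` (synergy pathway), `models`, and the echoed `config`.
#' @export
run_experiment <- function(config, truth = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$synth$seed
  truth <- truth %||% make_ground_truth(config$synth, config$separation)

  train_raw <- generate_session(config$synth, truth, "training")
  test_raw <- generate_session(config$synth, truth, "testing")
  train_env <- envelope(train_raw, mode = config$training_filter)

  syn_model <- NULL
  if (config$pathway == "synergy") {
    syn_model <- fit_synergy_model(train_env, k = config$synergy_k,
                                   variance_threshold = config$variance_threshold,
                                   slope_threshold = config$slope_threshold,
                                   seed = child_seed(seed, 31L))
    feats <- extract_synergy_features(train_env, syn_model, config$spec)
  } else {
    feats <- extract_emg_features(train_env, config$spec)
  }

  # Offline evaluation on a stratified split of the training trials
  # (whole trials, so the 90 %-overlapping windows never leak across
  # the split).
  trial_fit <- stratified_split(train_env$trials$class, config$offline_split,
                                child_seed(seed, 41L))
  in_train <- trial_fit[feats$trial]
  fit_set <- subset_features(feats, in_train)
  test_set <- subset_features(feats, !in_train)
  cv <- NULL
  n_hidden <- config$hidden_grid[1L]
  if (length(config$hidden_grid) > 1L) {
    cv <- elm_cv_select_hidden(fit_set, grid = config$hidden_grid,
                               lambda = config$lambda,
                               folds = config$cv_folds,
                               seed = child_seed(seed, 43L))
    n_hidden <- cv$best_n_hidden
  }
  off_model <- elm_fit(fit_set, n_hidden = n_hidden, lambda = config$lambda,
                       seed = child_seed(seed, 47L))
  off_pred <- elm_predict(off_model, test_set)
  offline <- list(
    accuracy = offline_accuracy(off_pred$class, test_set$labels),
    confusion = confusion_matrix(test_set$labels, off_pred$class),
    n_test = length(test_set$labels),
    n_hidden = n_hidden, cv = cv)

  # Final decoder trained on all training windows, then online phase.
  model <- elm_fit(feats, n_hidden = n_hidden, lambda = config$lambda,
                   seed = child_seed(seed, 53L))
  decoder <- online_decoder(model, config$pathway, syn_model)
  records <- run_testing_phase(decoder, test_raw, config$online)
  online <- online_report(records, classes = head(class_labels(config$synth), -1L),
                          seed = child_seed(seed, 59L))

  # Trial-to-trial variability from the testing-phase envelope traces.
  test_env <- envelope(test_raw, mode = "causal")
  varb <- vapply(head(class_labels(config$synth), -1L), function(cl) {
    idx <- which(test_env$trials$class == cl)
    variability(lapply(idx, function(i) trial_signal(test_env, i)))
  }, 0)

  result <- structure(list(
    offline = offline, online = online, variability = varb,
    records = records,
    feature_dim = nrow(feats$values),
    chosen_k = if (!is.null(syn_model)) syn_model$chosen_k else NA_integer_,
    models = list(elm = model, synergy = syn_model),
    config = config), class = "experiment_result")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_elm_model(model, file.path(config$out_dir, "elm_model.rds"))
    if (!is.null(syn_model))
      write_synergy_model(syn_model, file.path(config$out_dir, "synergy_model.rds"))
    write_features(feats, file.path(config$out_dir, "training_features.csv"))
    write.csv(records_summary(records),
              file.path(config$out_dir, "online_trials.csv"), row.names = FALSE)
    saveRDS(result, file.path(config$out_dir, "report.rds"))
  }
  result
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> pathway=%s, feature dim %d%s\n",
              x$config$pathway, x$feature_dim,
              if (!is.na(x$chosen_k)) sprintf(", %d synergies", x$chosen_k) else ""))
  cat(sprintf("  offline accuracy: %.2f %% (n_hidden = %d)\n",
              x$offline$accuracy, x$offline$n_hidden))
  print(x$online)
  invisible(x)
}
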