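#' Minimum-jerk positional profile
#'
#' The standard quintic minimum-jerk profile
#' `s(t) = 10 t^3 - 15 t^4 + 6 t^5` on normalized time `t` in \[0, 1\]:
#' the unique 5th-degree polynomial from 0 to 1 with zero velocity and
#' acceleration at both endpoints, used for the virtual arm's
#' point-to-point pose transitions.
#'
#' @param t normalized time, in \[0, 1\] (vectorized).
#' @return Positional fraction in \[0, 1\].
#' @export
minimum_jerk <- function(t) {
  if (any(t < 0 | t > 1)) stop_input("minimum_jerk: t must lie in [0, 1]")
  10 * t^3 - 15 * t^4 + 6 * t^5
}

#' Online simulation configuration
#'
#' @param spec a [window_spec()]; the ring buffer holds `window`
#'   samples and advances `step` samples per decoder tick.
#' @param debounce number of consecutive identical predictions required
#'   before the arm is (re)targeted; 1 reproduces raw per-tick behavior.
#' @param transition_duration seconds of one minimum-jerk pose change.
#' @param hold_duration seconds the target pose must be held to
#'   complete a trial.
#' @param timeout seconds after which an uncompleted trial is abandoned.
#' @return An `online_config` list.
#' @export
online_config <- function(spec = window_spec(), debounce = 5L,
                          transition_duration = 1.0, hold_duration = 0.5,
                          timeout = 30) {
  stopifnot(inherits(spec, "window_spec"))
  if (debounce < 1L) stop_input("debounce must be >= 1")
  if (transition_duration <= 0 || hold_duration <= 0 || timeout <= 0)
    stop_input("durations must be > 0")
  structure(list(spec = spec, debounce = as.integer(debounce),
                 transition_duration = transition_duration,
                 hold_duration = hold_duration, timeout = timeout),
            class = "online_config")
}

# Bundle a feature pathway and a trained ELM into a streaming decoder.
# pathway "emg": MAV+VAR per channel on the ring buffer; "synergy":
# window-mean envelope projected through the synergy model.
#' Build a streaming decoder from a trained model
#'
#' @param model a fitted `elm_model`.
#' @param pathway `"emg"` or `"synergy"`.
#' @param synergy_model a `synergy_model`, required for the synergy
#'   pathway.
#' @return An `online_decoder`.
#' @export
online_decoder <- function(model, pathway = c("emg", "synergy"),
                           synergy_model = NULL) {
  pathway <- match.arg(pathway)
  if (is.null(model$output_weights)) stop_input("decoder model is not trained")
  if (pathway == "synergy" && is.null(synergy_model))
    stop_input("synergy pathway needs a synergy_model")
  structure(list(model = model, pathway = pathway,
                 synergy_model = synergy_model),
            class = "online_decoder")
}

# Batch-decode every trailing window of an envelope stream.
# Causal by construction: the window ending at sample s uses samples
# (s - window + 1) .. s only. Returns per-tick predicted classes and
# the tick end-sample indices.
decode_stream <- function(decoder, stream, spec) {
  p <- nrow(stream)
  st <- window_starts(ncol(stream), spec)
  if (length(st) == 0L) stop_input("stream shorter than one window")
  ends <- st + spec$window - 1L
  if (decoder$pathway == "emg") {
    feats <- matrix(0, length(st), 2L * p)
    for (w in seq_along(st)) {
      win <- stream[, st[w]:ends[w], drop = FALSE]
      feats[w, ] <- c(rowMeans(abs(win)), rowSums(win^2) / (spec$window - 1))
    }
  } else {
    means <- vapply(seq_along(st), function(w)
      rowMeans(stream[, st[w]:ends[w], drop = FALSE]), numeric(p))
    feats <- t(project_online(decoder$synergy_model, matrix(means, nrow = p)))
  }
  pred <- elm_predict(decoder$model, feats)
  list(class = pred$class, ends = ends)
}

#' Run one simulated online trial
#'
#' Streams a causal envelope through the decoder at one prediction per
#' `step` samples (10 ms by default) and drives the virtual arm: a
#' predicted class sustained for `debounce` consecutive ticks
#' (re)targets a minimum-jerk transition; the trial is completed when
#' the arm reaches the commanded pose and holds it for
#' `hold_duration` seconds. Movement onset is the first tick whose raw
#' prediction is not rest; selection time the first tick predicting the
#' target, minus onset; completion time the completion instant minus
#' onset. A trial still incomplete at `timeout` (or at stream end) is
#' recorded as not completed.
#'
#' @param decoder an [online_decoder()].
#' @param stream causal envelope matrix (`p x samples`) for one
#'   commanded trial, including any trailing rest.
#' @param target_class the commanded class label.
#' @param config an [online_config()].
#' @param sample_rate stream sampling rate in Hz.
#' @return An `online_trial_record`: list with `target_class`,
#'   `decoder_outputs` (data.frame time/class), `pose_fraction`
#'   (per-tick arm positional fraction towards its current target),
#'   `movement_onset_time`, `selection_time`, `completion_time`,
#'   `completed`, `n_correct`, `n_wrong`.
#' @export
run_trial <- function(decoder, stream, target_class, config = online_config(),
                      sample_rate = 1000) {
  spec <- config$spec
  dec <- decode_stream(decoder, stream, spec)
  ticks <- length(dec$class)
  times <- dec$ends / sample_rate
  dt <- spec$step / sample_rate

  pose <- "rest"          # settled pose
  trans_target <- NA_character_
  trans_elapsed <- 0
  from_frac <- 0          # positional fraction at (re)targeting instant
  pose_frac <- numeric(ticks)   # fraction of the way to current target
  held_since <- NA_real_
  run <- 0L; run_class <- NA_character_
  completed <- FALSE
  completion_time_abs <- NA_real_

  for (i in seq_len(ticks)) {
    cls <- dec$class[i]
    if (identical(cls, run_class)) run <- run + 1L else { run_class <- cls; run <- 1L }
    # debounced command
    if (run >= config$debounce) {
      cmd <- run_class
      current_target <- if (!is.na(trans_target)) trans_target else pose
      if (!identical(cmd, current_target)) {
        # redirect: start a fresh transition from the current fraction
        from_frac <- if (!is.na(trans_target))
          from_frac + (1 - from_frac) * minimum_jerk(min(1, trans_elapsed / config$transition_duration))
        else 0
        trans_target <- cmd
        trans_elapsed <- 0
        held_since <- NA_real_
      }
    }
    if (!is.na(trans_target)) {
      trans_elapsed <- trans_elapsed + dt
      prog <- min(1, trans_elapsed / config$transition_duration)
      frac <- from_frac + (1 - from_frac) * minimum_jerk(prog)
      if (prog >= 1) {
        pose <- trans_target
        trans_target <- NA_character_
        held_since <- times[i]
        frac <- 1
      }
      pose_frac[i] <- frac
    } else {
      pose_frac[i] <- 1
    }
    if (is.na(trans_target) && identical(pose, target_class) &&
        !is.na(held_since) && times[i] - held_since >= config$hold_duration) {
      completed <- TRUE
      completion_time_abs <- times[i]
      pose_frac <- pose_frac[seq_len(i)]
      ticks <- i
      break
    }
    if (times[i] - times[1L] > config$timeout) {
      pose_frac <- pose_frac[seq_len(i)]
      ticks <- i
      break
    }
  }

  preds <- dec$class[seq_len(ticks)]
  tvec <- times[seq_len(ticks)]
  onset_i <- which(preds != "rest")[1L]
  onset <- if (is.na(onset_i)) NA_real_ else tvec[onset_i]
  sel_i <- which(preds == target_class)[1L]
  selection <- if (is.na(sel_i) || is.na(onset_i)) NA_real_ else tvec[sel_i] - onset
  completion <- if (completed && !is.na(onset)) completion_time_abs - onset else NA_real_
  span <- if (!is.na(onset_i)) onset_i:ticks else integer(0)
  n_correct <- sum(preds[span] == target_class)
  n_wrong <- length(span) - n_correct

  structure(list(target_class = target_class,
                 decoder_outputs = data.frame(time = tvec, class = preds,
                                              stringsAsFactors = FALSE),
                 pose_fraction = pose_frac,
                 movement_onset_time = onset,
                 selection_time = selection,
                 completion_time = completion,
                 completed = completed,
                 n_correct = n_correct, n_wrong = n_wrong),
            class = "online_trial_record")
}

#' Run the full simulated testing phase
#'
#' Filters the raw testing session causally to envelopes, then runs one
#' online trial per commanded motion trial in session order. Each
#' trial's stream spans from the trial start to the start of the next
#' trial (i.e. it includes the trailing rest period in which the
#' subject would settle the arm).
#'
#' @param decoder an [online_decoder()].
#' @param session a raw testing-phase `emg_session`.
#' @param config an [online_config()].
#' @param rep_index optional subset of trial rows to simulate.
#' @return List of `online_trial_record`s (one per motion trial).
#' @export
run_testing_phase <- function(decoder, session, config = online_config(),
                              rep_index = NULL) {
  if (!identical(session$phase, "testing"))
    warning("session is not marked as a testing phase")
  env <- envelope(session, mode = "causal")
  idx <- rep_index %||% seq_len(nrow(session$trials))
  lapply(idx, function(i) {
    tr <- env$trials[i, ]
    stop_at <- if (i < nrow(env$trials)) env$trials$start[i + 1L] - 1L
               else ncol(env$signal)
    stream <- env$signal[, tr$start:stop_at, drop = FALSE]
    run_trial(decoder, stream, tr$class, config,
              sample_rate = session$sample_rate)
  })
}

#' Summarize online trial records as one row per trial
#'
#' @param records list of `online_trial_record`s.
#' @return data.frame with target class, onset/selection/completion
#'   times, completion flag and per-trial correct/incorrect tick counts.
#' @export
records_summary <- function(records) {
  data.frame(
    target_class = vapply(records, `[[`, "", "target_class"),
    movement_onset_time = vapply(records, `[[`, 0, "movement_onset_time"),
    selection_time = vapply(records, `[[`, 0, "selection_time"),
    completion_time = vapply(records, `[[`, 0, "completion_time"),
    completed = vapply(records, `[[`, TRUE, "completed"),
    n_correct = vapply(records, `[[`, 0, "n_correct"),
    n_wrong = vapply(records, `[[`, 0, "n_wrong"),
    stringsAsFactors = FALSE)
}
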