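# A deterministic "stream" built directly from a tiny trained decoder is
# expensive to control, so the state-machine tests drive run_trial with
# a stub decoder whose predictions are fixed in advance.
stub_decoder <- function(classes) {
  structure(list(model = structure(list(output_weights = 1), class = "elm_model"),
                 pathway = "emg", predictions = classes),
            class = c("stub_decoder", "online_decoder"))
}

# run_trial consumes decode_stream; route the stub through it.
with_stub <- function(preds, stream_len = NULL, config = online_config(),
                      target = "motion1", sr = 100) {
  spec <- config$spec
  n <- length(preds)
  stream <- matrix(0, 2, spec$window + (n - 1) * spec$step)
  dec <- stub_decoder(preds)
  testthat::with_mocked_bindings(
    decode_stream = function(decoder, stream, spec) {
      ends <- window_starts(ncol(stream), spec) + spec$window - 1L
      list(class = decoder$predictions, ends = ends)
    },
    run_trial(dec, stream, target, config, sample_rate = sr),
    .package = "myodecode")
}

test_that("minimum-jerk profile has the right boundary behavior", {
  expect_equal(minimum_jerk(0), 0)
  expect_equal(minimum_jerk(1), 1)
  expect_equal(minimum_jerk(0.5), 0.5)
  # first and second derivatives vanish at both ends:
  # s'(t) = 30t^2 - 60t^3 + 30t^4, s''(t) = 60t - 180t^2 + 120t^3
  d1 <- function(t) 30 * t^2 - 60 * t^3 + 30 * t^4
  d2 <- function(t) 60 * t - 180 * t^2 + 120 * t^3
  expect_equal(c(d1(0), d1(1), d2(0), d2(1)), c(0, 0, 0, 0))
  # and numerically, the profile matches those derivatives
  h <- 1e-6
  expect_equal((minimum_jerk(h) - minimum_jerk(0)) / h, 0, tolerance = 1e-5)
  expect_equal((minimum_jerk(1) - minimum_jerk(1 - h)) / h, 0, tolerance = 1e-5)
  expect_true(all(diff(minimum_jerk(seq(0, 1, 0.01))) >= 0))
  expect_error(minimum_jerk(1.2), "\\[0, 1\\]")
})

test_that("an oracle decoder selects immediately and completes after transition + hold", {
  cfg <- online_config(spec = window_spec(20L, 10L), debounce = 1L,
                       transition_duration = 0.5, hold_duration = 0.5)
  sr <- 100  # 10 Hz tick rate: dt = 0.1 s
  rec <- with_stub(rep("motion1", 60), config = cfg, sr = sr)
  expect_true(rec$completed)
  expect_equal(rec$selection_time, 0)
  # transition 0.5 s + hold 0.5 s, quantized to the 0.1 s tick
  expect_equal(rec$completion_time, 1.0, tolerance = 0.2 + 1e-9)
  expect_equal(rec$n_wrong, 0)
  expect_gt(rec$n_correct, 0)
})

test_that("a decoder that never outputs the target never completes", {
  cfg <- online_config(spec = window_spec(20L, 10L), debounce = 2L,
                       transition_duration = 0.3, timeout = 2)
  rec <- with_stub(rep("motion2", 80), config = cfg, target = "motion1")
  expect_false(rec$completed)
  expect_true(is.na(rec$completion_time))
  expect_equal(rec$n_correct, 0)
  expect_gt(rec$n_wrong, 0)
})

test_that("onset is the first non-rest prediction and selection the first target hit", {
  cfg <- online_config(spec = window_spec(20L, 10L), debounce = 1L,
                       transition_duration = 0.3)
  preds <- c(rep("rest", 5), rep("motion2", 3), rep("motion1", 40))
  rec <- with_stub(preds, config = cfg, sr = 100)
  # tick times are window ends: tick i at (20 + 10(i-1))/100 s
  t_of <- function(i) (20 + 10 * (i - 1)) / 100
  expect_equal(rec$movement_onset_time, t_of(6))
  expect_equal(rec$selection_time, t_of(9) - t_of(6))
  expect_true(rec$completed)
  # correctness counted from onset to completion
  n_ticks <- nrow(rec$decoder_outputs)
  expect_equal(rec$n_correct + rec$n_wrong, n_ticks - 5)
})

test_that("debouncing suppresses isolated flickers", {
  cfg <- online_config(spec = window_spec(20L, 10L), debounce = 3L,
                       transition_duration = 0.3, hold_duration = 0.3)
  # single-tick flickers to motion2 never last 3 ticks, so the arm goes
  # to motion1 regardless
  preds <- rep(c("motion1", "motion1", "motion1", "motion2"), 15)
  rec <- with_stub(preds, config = cfg, sr = 100)
  expect_true(rec$completed)
  # with debounce 1 the same stream chatters and never holds long enough
  cfg1 <- online_config(spec = window_spec(20L, 10L), debounce = 1L,
                        transition_duration = 0.3, hold_duration = 0.3)
  rec1 <- with_stub(preds, config = cfg1, sr = 100)
  expect_false(rec1$completed)
})

test_that("arm position never jumps within a transition", {
  cfg <- online_config(spec = window_spec(20L, 10L), debounce = 1L,
                       transition_duration = 0.5, hold_duration = 0.4)
  preds <- c(rep("motion1", 3), rep("motion2", 4), rep("motion1", 50))
  rec <- with_stub(preds, config = cfg, sr = 100)
  frac <- rec$pose_fraction
  # per-tick fraction increments are bounded by the max min-jerk slope
  # (15/8 at t = 1/2) times dt/duration
  dt <- 0.1
  max_step <- 15 / 8 * dt / cfg$transition_duration + 1e-9
  steps <- diff(frac)
  expect_true(all(steps[steps > 0] <= max_step))
})

test_that("full testing phase yields one record per motion trial", {
  fx <- tiny_session(seed = 30, phase = "training")
  env <- envelope(fx$session)
  fm <- extract_emg_features(env, tiny_spec())
  model <- elm_fit(fm, n_hidden = 150, seed = 31)
  dec <- online_decoder(model, "emg")
  test_s <- generate_session(fx$config, fx$truth, "testing")
  cfg <- online_config(spec = tiny_spec(), transition_duration = 0.5)
  recs <- run_testing_phase(dec, test_s, cfg)
  expect_length(recs, nrow(test_s$trials))
  expect_equal(vapply(recs, `[[`, "", "target_class"), test_s$trials$class)
  tab <- table(vapply(recs, `[[`, "", "target_class"))
  expect_true(all(tab == fx$config$reps_test))
  # determinism: the same decoder and session give identical records
  recs2 <- run_testing_phase(dec, test_s, cfg)
  expect_identical(recs, recs2)
  # selection <= completion on completed trials
  summ <- records_summary(recs)
  done <- summ[summ$completed, ]
  expect_true(all(done$selection_time <= done$completion_time + 1e-12))
})

test_that("causality: decisions only use past samples", {
  fx <- tiny_session(seed = 32, phase = "training")
  env <- envelope(fx$session)
  fm <- extract_emg_features(env, tiny_spec())
  model <- elm_fit(fm, n_hidden = 100, seed = 33)
  dec <- online_decoder(model, "emg")
  stream <- envelope(generate_session(fx$config, fx$truth, "testing"),
                     mode = "causal")$signal[, 1:400]
  out1 <- myodecode:::decode_stream(dec, stream, tiny_spec())
  # corrupting the future does not change past decisions
  stream2 <- stream
  stream2[, 301:400] <- 10
  out2 <- myodecode:::decode_stream(dec, stream2, tiny_spec())
  past <- out1$ends <= 300
  expect_identical(out1$class[past], out2$class[past])
})

test_that("decoder construction validates its inputs", {
  fx <- tiny_session(seed = 34)
  fm <- extract_emg_features(envelope(fx$session), tiny_spec())
  model <- elm_fit(fm, n_hidden = 50, seed = 35)
  expect_error(online_decoder(model, "synergy"), "synergy_model")
  untrained <- model
  untrained$output_weights <- NULL
  expect_error(online_decoder(untrained, "emg"), "not trained")
})
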