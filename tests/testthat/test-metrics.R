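fake_record <- function(target = "motion1", completed = TRUE,
                        n_correct = 8, n_wrong = 2, completion = 2,
                        selection = 0.1) {
  structure(list(target_class = target,
                 decoder_outputs = data.frame(
                   time = seq_len(n_correct + n_wrong) / 10,
                   class = c(rep(target, n_correct),
                             rep("other", n_wrong))),
                 movement_onset_time = 0.1,
                 selection_time = selection, completion_time = completion,
                 completed = completed,
                 n_correct = n_correct, n_wrong = n_wrong),
            class = "online_trial_record")
}

test_that("offline accuracy is the correct-sample percentage", {
  expect_equal(offline_accuracy(c("a", "b"), c("a", "b")), 100)
  expect_equal(offline_accuracy(c("a", "b"), c("b", "a")), 0)
  expect_equal(offline_accuracy(c("a", "a", "a", "b"), c("a", "a", "a", "a")), 75)
  expect_error(offline_accuracy(character(0), character(0)), "non-empty")
  expect_error(offline_accuracy("a", c("a", "b")), "equal-length")
})

test_that("online accuracy averages per-trial fractions over completed trials", {
  recs <- list(fake_record(n_correct = 5, n_wrong = 5),    # 0.5
               fake_record(n_correct = 7, n_wrong = 0))    # 1.0
  expect_equal(online_accuracy(recs, "motion1"), 75)
  # incomplete trials are excluded
  recs2 <- c(recs, list(fake_record(completed = FALSE, n_correct = 0,
                                    n_wrong = 10)))
  expect_equal(online_accuracy(recs2, "motion1"), 75)
  # no completed trial: undefined, not zero
  expect_true(is.na(online_accuracy(list(fake_record(completed = FALSE)),
                                    "motion1")))
  # degenerate completed trial with no outputs between onset and
  # completion is dropped with a warning
  recs3 <- c(recs, list(fake_record(n_correct = 0, n_wrong = 0)))
  expect_warning(acc <- online_accuracy(recs3, "motion1"), "no decoder output")
  expect_equal(acc, 75)
  expect_equal(online_accuracy(recs, "motion9"), NA_real_)
})

test_that("learning trend recovers exponential decay parameters", {
  x <- 1:20
  y <- 2 * exp(-0.3 * x) + 1
  fit <- fit_learning_trend(y)
  expect_true(fit$converged)
  expect_true(fit$identifiable)
  expect_equal(fit$a, 2, tolerance = 1e-6)
  expect_equal(fit$b, 0.3, tolerance = 1e-6)
  expect_equal(fit$c, 1, tolerance = 1e-6)
  expect_lt(fit$residual_norm, 1e-8)
})

test_that("constant completion times give an unidentifiable flat fit", {
  fit <- fit_learning_trend(rep(2.5, 12))
  expect_true(fit$converged)
  expect_false(fit$identifiable)
  expect_equal(fit$a * exp(-fit$b * 6) + fit$c, 2.5, tolerance = 1e-6)
})

test_that("learning rate is recovered within 0.1 under noise", {
  set.seed(99)
  errs <- replicate(60, {
    x <- 1:20
    y <- 2 * exp(-0.3 * x) + 1 + rnorm(20, sd = 0.1)
    fit_learning_trend(y)$b - 0.3
  })
  # the bulk of replicates land within +/- 0.1 of the true rate
  expect_gt(mean(abs(errs) <= 0.1), 0.9)
  expect_lt(abs(mean(errs)), 0.05)
})

test_that("fit_learning_trend rejects too-few points", {
  expect_error(fit_learning_trend(c(1, 2, 3)), ">= 4")
})

test_that("variability matches the population-sd definition", {
  p <- 3
  # identical repetitions: zero variability
  reps <- replicate(5, matrix(runif(p * 30), p, 30), simplify = FALSE)
  same <- replicate(5, reps[[1]], simplify = FALSE)
  expect_equal(variability(same), 0)
  # two constant repetitions at 0 and 2: sd = 1 everywhere (divisor nRep)
  two <- list(matrix(0, 2, 50), matrix(2, 2, 50))
  expect_equal(variability(two), 1)
  # invariant to repetition order and channel order
  set.seed(5)
  reps <- replicate(4, matrix(runif(2 * 40), 2, 40), simplify = FALSE)
  v1 <- variability(reps)
  expect_equal(variability(rev(reps)), v1)
  flipped <- lapply(reps, function(m) m[2:1, ])
  expect_equal(variability(flipped), v1)
  expect_error(variability(reps[1]), "2 repetitions")
})

test_that("variability resamples different-length repetitions onto 200 points", {
  # same underlying ramp sampled at different rates: variability ~ 0
  ramp <- function(L) matrix(seq(0, 1, length.out = L), 1)
  v <- variability(list(ramp(100), ramp(333), ramp(50)))
  expect_lt(v, 1e-3)
})

test_that("confusion matrix is row-normalized with actual classes as rows", {
  act <- c("a", "a", "b", "b")
  prd <- c("a", "b", "b", "b")
  cm <- confusion_matrix(act, prd)
  expect_equal(rowSums(cm), c(a = 100, b = 100))
  expect_equal(cm["a", "a"], 50)
  expect_equal(cm["b", "b"], 100)
  # perfect predictions: identity x 100
  cm2 <- confusion_matrix(act, act)
  expect_equal(unname(cm2), diag(2) * 100)
  # uniform random predictions approach 100/m per cell
  set.seed(31)
  cls <- letters[1:6]
  a <- rep(cls, each = 1e4)
  p2 <- sample(cls, 6e4, replace = TRUE)
  cm3 <- confusion_matrix(a, p2)
  expect_true(all(abs(cm3 - 100 / 6) < 2))
  expect_error(confusion_matrix(character(0), character(0)), "non-empty")
})

test_that("offline accuracy equals the trace identity of the confusion counts", {
  set.seed(8)
  act <- sample(letters[1:4], 500, replace = TRUE)
  prd <- act
  flip <- sample(500, 120)
  prd[flip] <- sample(letters[1:4], 120, replace = TRUE)
  cm_counts <- table(factor(act, letters[1:4]), factor(prd, letters[1:4]))
  expect_equal(offline_accuracy(prd, act),
               100 * sum(diag(cm_counts)) / length(act))
})

test_that("online report aggregates per-class metrics", {
  recs <- list(fake_record("motion1", n_correct = 5, n_wrong = 5),
               fake_record("motion1", n_correct = 7, n_wrong = 0),
               fake_record("motion2", completed = FALSE),
               fake_record("motion2", n_correct = 4, n_wrong = 0))
  rep <- online_report(recs, classes = c("motion1", "motion2"))
  expect_equal(rep$per_class$motion1$online_accuracy, 75)
  expect_equal(rep$per_class$motion1$completion_rate, 100)
  expect_equal(rep$per_class$motion2$completion_rate, 50)
  expect_equal(rep$overall_completion_rate, 75)
  expect_equal(dim(rep$confusion), c(3L, 3L))  # motion1, motion2, other
})
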