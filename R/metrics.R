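#' Offline classification accuracy
#'
#' `Acc_off = n_c / (n_c + n_w) * 100`: the percentage of feature
#' windows assigned to their true motion class.
#'
#' @param predicted,actual equal-length label vectors.
#' @return Percent accuracy in \[0, 100\].
#' @export
offline_accuracy <- function(predicted, actual) {
  if (length(predicted) == 0L || length(predicted) != length(actual))
    stop_input("offline_accuracy: need equal-length, non-empty label vectors")
  100 * mean(predicted == actual)
}

#' Online classification accuracy of a motion class
#'
#' `Acc_on = (1/N) * sum_i n_i / (n_i + m_i) * 100` over the `N`
#' successfully completed trials of the class: the mean, across
#' completed trials, of the fraction of decoder outputs between
#' movement onset and completion that match the commanded class.
#' Trials that were not completed are excluded; a class with no
#' completed trial yields `NA` (undefined, not zero). Degenerate
#' completed trials with no decoder output between onset and completion
#' are excluded with a warning.
#'
#' @param records list of `online_trial_record`s.
#' @param class motion-class label; `NULL` pools every completed trial.
#' @return Percent accuracy, or `NA_real_` when undefined.
#' @export
online_accuracy <- function(records, class = NULL) {
  keep <- vapply(records, function(r) {
    r$completed && (is.null(class) || identical(r$target_class, class))
  }, TRUE)
  recs <- records[keep]
  if (length(recs) == 0L) return(NA_real_)
  tot <- vapply(recs, function(r) r$n_correct + r$n_wrong, 0)
  if (any(tot == 0)) {
    warning("excluding ", sum(tot == 0), " completed trial(s) with no decoder output")
    recs <- recs[tot > 0]
    if (length(recs) == 0L) return(NA_real_)
  }
  fr <- vapply(recs, function(r) r$n_correct / (r$n_correct + r$n_wrong), 0)
  100 * mean(fr)
}

#' Exponential learning trend of completion times
#'
#' Fits `y(x) = a * exp(-b x) + c` to per-repetition completion times
#' `x = 1..n` by multi-start bounded nonlinear least squares
#' (Levenberg-Marquardt, three seeded starts, `b` bounded to
#' \[-5, 5\]). `a` is the initial performance offset, `b` the learning
#' rate and `c` the steady-state completion time; with this
#' parameterization a positive `b` means completion times decay, i.e.
#' learning. For near-constant data `b` is unidentifiable; the fit is
#' then flagged (`identifiable = FALSE`) rather than trusted.
#'
#' @param y completion times (>= 4 finite values).
#' @param x repetition indices (default `1..length(y)`).
#' @param seed seed for the randomized extra starts.
#' @return List with `a`, `b`, `c`, `residual_norm`, `converged`,
#'   `identifiable`.
#' @export
fit_learning_trend <- function(y, x = seq_along(y), seed = 1L) {
  keep <- is.finite(y)
  y <- y[keep]; x <- x[keep]
  if (length(y) < 4L) stop_input("fit_learning_trend: need >= 4 points")
  spread <- diff(range(y))
  starts <- list(c(a = max(y[1] - min(y), 0.1), b = 0.1, c = min(y)))
  extra <- with_seed(child_seed(seed, 7L), replicate(2, {
    c(a = runif(1, -1, 1) * max(spread, 0.1), b = runif(1, -2, 2),
      c = mean(y) + runif(1, -0.5, 0.5) * max(spread, 0.1))
  }, simplify = FALSE))
  starts <- c(starts, extra)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-b * x) + c,
                        start = as.list(s),
                        lower = c(a = -Inf, b = -5, c = -Inf),
                        upper = c(a = Inf, b = 5, c = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(residuals(fit)^2))
    if (is.null(best) || rn < best$residual_norm) {
      co <- coef(fit)
      best <- list(a = unname(co["a"]), b = unname(co["b"]),
                   c = unname(co["c"]), residual_norm = rn, converged = TRUE)
    }
  }
  if (is.null(best))
    return(list(a = NA_real_, b = NA_real_, c = NA_real_,
                residual_norm = NA_real_, converged = FALSE,
                identifiable = FALSE))
  # b is unidentifiable when the exponential term contributes nothing
  best$identifiable <- is.finite(best$a) &&
    abs(best$a) * abs(exp(-best$b * x[1]) - exp(-best$b * x[length(x)])) >
      1e-8 * max(1, abs(best$c))
  best
}

#' Trial-to-trial variability of muscle activity
#'
#' Each repetition's multi-channel envelope trace is linearly
#' time-normalized (0 = movement start, 1 = completion) and resampled
#' to a common 200 samples; at every channel and normalized time point
#' the population standard deviation across repetitions (divisor
#' `nRep`) is computed, and the result is the grand mean over channels
#' and time points. Lower values indicate more consistent muscle
#' activity across repetitions.
#'
#' @param trial_envelopes list of `p x L_r` matrices, one per
#'   repetition (lengths may differ).
#' @param n_samples number of resampled time points.
#' @param interpolation `"linear"` or `"constant"` (see
#'   [stats::approx()]).
#' @return Non-negative scalar variability.
#' @export
variability <- function(trial_envelopes, n_samples = 200L,
                        interpolation = c("linear", "constant")) {
  interpolation <- match.arg(interpolation)
  n_rep <- length(trial_envelopes)
  if (n_rep < 2L) stop_input("variability: need >= 2 repetitions")
  p <- nrow(trial_envelopes[[1L]])
  grid <- seq(0, 1, length.out = n_samples)
  E <- array(0, c(n_rep, p, n_samples))
  for (r in seq_len(n_rep)) {
    tr <- trial_envelopes[[r]]
    if (nrow(tr) != p) stop_input("variability: channel mismatch")
    L <- ncol(tr)
    if (L < 2L) stop_input("variability: repetition with < 2 samples")
    tt <- seq(0, 1, length.out = L)
    for (ch in seq_len(p))
      E[r, ch, ] <- approx(tt, tr[ch, ], xout = grid,
                           method = interpolation, rule = 2)$y
  }
  mu <- apply(E, c(2L, 3L), mean)
  sig <- sqrt(apply(sweep(E, c(2L, 3L), mu)^2, c(2L, 3L), mean))
  mean(sig)
}

#' Row-normalized confusion matrix
#'
#' Rows are the actual (requested) classes, columns the predicted
#' classes; each row is normalized to sum to 100 so entry (i, j) is the
#' percentage of class-i samples decoded as class j.
#'
#' @param actual,predicted label vectors of equal length.
#' @param classes class order; default sorted union.
#' @return `m x m` matrix of percentages.
#' @export
confusion_matrix <- function(actual, predicted, classes = NULL) {
  if (length(actual) == 0L || length(actual) != length(predicted))
    stop_input("confusion_matrix: need equal-length, non-empty labels")
  classes <- classes %||% sort(union(actual, predicted))
  tab <- table(factor(actual, classes), factor(predicted, classes))
  counts <- matrix(as.numeric(tab), nrow = length(classes),
                   dimnames = list(actual = classes, predicted = classes))
  rs <- rowSums(counts)
  rs[rs == 0] <- 1
  100 * counts / rs
}

#' Compile a full per-class performance report from online records
#'
#' @param records list of `online_trial_record`s.
#' @param classes motion-class order for the per-class tables.
#' @param seed seed for the learning-trend fits.
#' @return A `performance_report` list: per-class online accuracy,
#'   selection/completion time mean and sd, completion rate, learning
#'   trend parameters, and the pooled online confusion matrix (from
#'   per-tick decoder outputs of all trials).
#' @export
online_report <- function(records, classes = NULL, seed = 1L) {
  summ <- records_summary(records)
  classes <- classes %||% sort(unique(summ$target_class))
  per <- lapply(classes, function(cl) {
    rows <- summ[summ$target_class == cl, ]
    done <- rows[rows$completed, ]
    trend <- if (sum(is.finite(done$completion_time)) >= 4L)
      fit_learning_trend(done$completion_time, seed = seed) else NULL
    list(class = cl,
         n_trials = nrow(rows),
         completion_rate = 100 * mean(rows$completed),
         online_accuracy = online_accuracy(records, cl),
         selection_time_mean = mean(done$selection_time, na.rm = TRUE),
         selection_time_sd = sd(done$selection_time, na.rm = TRUE),
         completion_time_mean = mean(done$completion_time, na.rm = TRUE),
         completion_time_sd = sd(done$completion_time, na.rm = TRUE),
         learning_trend = trend)
  })
  names(per) <- classes
  act <- unlist(lapply(records, function(r)
    rep(r$target_class, nrow(r$decoder_outputs))))
  prd <- unlist(lapply(records, function(r) r$decoder_outputs$class))
  structure(list(per_class = per,
                 overall_online_accuracy = online_accuracy(records),
                 overall_completion_rate = 100 * mean(summ$completed),
                 mean_selection_time =
                   mean(summ$selection_time[summ$completed], na.rm = TRUE),
                 mean_completion_time =
                   mean(summ$completion_time[summ$completed], na.rm = TRUE),
                 confusion = confusion_matrix(act, prd)),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("<performance_report> online accuracy %.2f %%, completion rate %.1f %%\n",
              x$overall_online_accuracy, x$overall_completion_rate))
  cat(sprintf("  mean selection time %.3f s, mean completion time %.3f s\n",
              x$mean_selection_time, x$mean_completion_time))
  invisible(x)
}
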