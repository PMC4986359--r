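#' Sliding-window specification
#'
#' Defaults match the standard real-time decoding setup: 100-sample
#' (100 ms at 1 kHz) windows advanced by 10 samples, i.e. 90 samples of
#' overlap, so a decoder output is produced every 10 ms.
#'
#' @param window window length in samples.
#' @param step window advance in samples; `window - step` is the overlap.
#' @return A `window_spec` list.
#' @export
window_spec <- function(window = 100L, step = 10L) {
  window <- as.integer(window); step <- as.integer(step)
  if (step < 1L || step > window)
    stop_input("need 0 < step <= window")
  structure(list(window = window, step = step), class = "window_spec")
}

#' Mean absolute value of a window
#'
#' `MAV = (1/N) * sum(|x_n|)`: the average rectified amplitude, an
#' indicator of movement duration and effort.
#'
#' @param x numeric vector of window samples (N >= 1).
#' @return Scalar MAV.
#' @export
mav <- function(x) {
  if (length(x) < 1L) stop_input("mav: empty window")
  mean(abs(x))
}

#' Uncentered variance of a window
#'
#' `VAR = (1/(N-1)) * sum(x_n^2)`: a power measure used to detect
#' movement onset and contraction intensity. Note this is the mean
#' square with an `N-1` divisor, with no mean subtraction — the form
#' conventionally used as an EMG power feature — so it is not the
#' statistical variance ([stats::var()]).
#'
#' @param x numeric vector of window samples (N >= 2).
#' @return Scalar VAR.
#' @export
emg_var <- function(x) {
  n <- length(x)
  if (n < 2L) stop_input("emg_var: need at least 2 samples")
  sum(x^2) / (n - 1)
}

# Start indices (1-based) of sliding windows fully inside a segment of
# length len; floor((len - window)/step) + 1 windows.
window_starts <- function(len, spec) {
  if (len < spec$window) return(integer(0))
  seq.int(1L, len - spec$window + 1L, by = spec$step)
}

#' Extract sliding-window time-domain EMG features
#'
#' For every labeled trial segment, slides a window (never straddling
#' segment boundaries) and computes MAV and VAR per channel. The feature
#' layout is fixed: all channel MAVs first, then all channel VARs, in
#' channel order, so a 7-channel session yields 14-dimensional feature
#' vectors.
#'
#' @param session an envelope `emg_session` (see [envelope()]).
#' @param spec a [window_spec()].
#' @return A `feature_matrix`: list with `values` (feature dim x
#'   n_windows), `labels` (per-window class), `trial` (per-window trial
#'   row index), `window_end` (per-window end sample, session indexing),
#'   `feature_kind = "emg"` and `feature_names`.
#' @export
extract_emg_features <- function(session, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  p <- nrow(session$signal)
  vals <- list(); labs <- list(); ends <- list(); tri <- list()
  for (i in seq_len(nrow(session$trials))) {
    tr <- session$trials[i, ]
    len <- tr$end - tr$start
    st <- window_starts(len, spec)
    if (length(st) == 0L) {
      warning("trial ", i, " shorter than window; skipped")
      next
    }
    seg <- session$signal[, tr$start:(tr$end - 1L), drop = FALSE]
    m <- matrix(0, 2L * p, length(st))
    for (w in seq_along(st)) {
      win <- seg[, st[w]:(st[w] + spec$window - 1L), drop = FALSE]
      m[seq_len(p), w] <- rowMeans(abs(win))
      m[p + seq_len(p), w] <- rowSums(win^2) / (spec$window - 1)
    }
    vals[[length(vals) + 1L]] <- m
    labs[[length(labs) + 1L]] <- rep(tr$class, length(st))
    ends[[length(ends) + 1L]] <- tr$start - 1L + st + spec$window - 1L
    tri[[length(tri) + 1L]] <- rep(i, length(st))
  }
  if (length(vals) == 0L) stop_input("no trial long enough for one window")
  structure(list(values = do.call(cbind, vals),
                 labels = unlist(labs),
                 trial = unlist(tri),
                 window_end = unlist(ends),
                 feature_kind = "emg",
                 feature_names = c(paste0("mav_ch", seq_len(p)),
                                   paste0("var_ch", seq_len(p)))),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> kind=%s, dim=%d, windows=%d, classes=%d\n",
              x$feature_kind, nrow(x$values), ncol(x$values),
              length(unique(x$labels))))
  invisible(x)
}

#' Write a feature matrix as a CSV table with a feature-name header
#'
#' One row per window: feature columns, then `class`, `trial`,
#' `window_end`.
#'
#' @param fm a `feature_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_features <- function(fm, path) {
  df <- as.data.frame(t(fm$values))
  names(df) <- fm$feature_names
  df$class <- fm$labels
  df$trial <- fm$trial
  df$window_end <- fm$window_end
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
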