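#' Compute the EMG envelope of a session
#'
#' Full-wave rectification followed by a 4th-order Butterworth low-pass
#' filter at `cutoff` Hz, the standard surface-EMG envelope. Two
#' variants are provided: `mode = "offline"` applies the filter
#' forward-backward (zero phase, used when processing training data),
#' `mode = "causal"` applies it in a single forward pass and is the one
#' the online simulator uses, since a real-time loop cannot look ahead.
#' Negative values produced by filter undershoot are clipped to zero so
#' the result is a valid non-negative envelope (required by the
#' non-negative factorization downstream).
#'
#' @param session an `emg_session`.
#' @param mode `"offline"` (zero-phase) or `"causal"` (single pass).
#' @param cutoff low-pass cutoff in Hz; must be below Nyquist.
#' @param order Butterworth order.
#' @return An `emg_session` whose `signal` holds non-negative envelope
#'   values; trial table and metadata are preserved.
#' @export
envelope <- function(session, mode = c("offline", "causal"),
                     cutoff = 10, order = 4L) {
  mode <- match.arg(mode)
  stopifnot(inherits(session, "emg_session"))
  nyq <- session$sample_rate / 2
  if (cutoff >= nyq)
    stop_input("cutoff (", cutoff, " Hz) must be below Nyquist (", nyq, " Hz)")
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  rect <- abs(session$signal)
  out <- rect
  for (ch in seq_len(nrow(rect))) {
    x <- rect[ch, ]
    y <- if (mode == "offline") {
      signal::filtfilt(bf, x)
    } else {
      as.numeric(signal::filter(bf, x))
    }
    out[ch, ] <- pmax(y, 0)
  }
  session$signal <- out
  session$envelope_mode <- mode
  session
}
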