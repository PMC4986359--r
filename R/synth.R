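#' Configuration of a synthetic EMG recording session
#'
#' Bundles all protocol and noise parameters of the synthetic
#' multi-channel surface-EMG generator. The defaults mirror the standard
#' upper-limb decoding protocol: 7 EMG channels sampled at 1 kHz, five
#' motion classes plus a rest class, 3 s trials separated by 2 s rest,
#' 10 repetitions per class during training and 20 during testing.
#'
#' @param n_channels number of EMG channels (muscles).
#' @param sample_rate sampling rate in Hz.
#' @param n_classes total number of classes including rest; the last
#'   class is always the rest class.
#' @param n_true_synergies number of planted non-negative synergy basis
#'   vectors; must not exceed `n_channels`.
#' @param trial_duration duration of one movement trial in seconds.
#' @param rest_duration inter-trial rest duration in seconds.
#' @param reps_train repetitions of each class in the training phase.
#' @param reps_test repetitions of each motion class in the testing phase.
#' @param noise_sd standard deviation of the additive zero-mean Gaussian
#'   noise on the raw signal, in envelope units.
#' @param rep_variability fractional per-repetition amplitude jitter:
#'   each repetition is scaled by `1 + rep_variability * z`, `z ~ N(0,1)`
#'   (clamped to stay positive).
#' @param seed integer seed controlling all randomness in the generator.
#'
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_channels = 7L, sample_rate = 1000,
                         n_classes = 6L, n_true_synergies = 4L,
                         trial_duration = 3.0, rest_duration = 2.0,
                         reps_train = 10L, reps_test = 20L,
                         noise_sd = 0.02, rep_variability = 0.1,
                         seed = 1L) {
  cfg <- list(
    n_channels = as.integer(n_channels), sample_rate = sample_rate,
    n_classes = as.integer(n_classes),
    n_true_synergies = as.integer(n_true_synergies),
    trial_duration = trial_duration, rest_duration = rest_duration,
    reps_train = as.integer(reps_train), reps_test = as.integer(reps_test),
    noise_sd = noise_sd, rep_variability = rep_variability,
    seed = as.integer(seed)
  )
  if (cfg$n_true_synergies > cfg$n_channels)
    stop_input("n_true_synergies must not exceed n_channels")
  if (cfg$n_classes < 2L)
    stop_input("need at least one motion class plus rest")
  pos <- c("sample_rate", "trial_duration", "rest_duration")
  for (f in pos)
    if (cfg[[f]] <= 0) stop_input(f, " must be > 0")
  if (cfg$reps_train < 1L || cfg$reps_test < 1L || cfg$n_channels < 1L)
    stop_input("counts must be >= 1")
  if (cfg$noise_sd < 0 || cfg$rep_variability < 0)
    stop_input("noise_sd and rep_variability must be >= 0")
  class(cfg) <- "synth_config"
  cfg
}

#' Class labels of a synthetic session
#'
#' Motion classes are named `motion1 ... motionK`; the final class is
#' `rest`.
#'
#' @param config a [synth_config()].
#' @return Character vector of class labels, rest last.
#' @export
class_labels <- function(config) {
  c(paste0("motion", seq_len(config$n_classes - 1L)), "rest")
}

#' Generate the ground-truth synergy structure of a synthetic subject
#'
#' Draws a random non-negative synergy basis (one column per planted
#' synergy, unit Euclidean norm) and one smooth activation time course
#' per class and synergy. Activation profiles are raised-cosine (Hann)
#' bumps spanning the trial, scaled by a per-class synergy-weight vector.
#' The `separation` parameter controls how distinct the class codes are:
#' at 0 every motion class shares one weight vector (decoding is
#' impossible beyond chance); large values push the codes towards
#' near-orthogonal corners of the non-negative orthant. The rest class
#' has an all-zero profile.
#'
#' @param config a [synth_config()].
#' @param separation non-negative scalar controlling between-class
#'   distinctness of the synergy-weight vectors.
#' @return An object of class `ground_truth` with fields `basis`
#'   (`n_channels x n_true_synergies`), `class_activation_profiles`
#'   (list per class of `n_true_synergies x trial_samples` matrices) and
#'   `class_labels`.
#' @export
make_ground_truth <- function(config, separation = 4) {
  stopifnot(inherits(config, "synth_config"))
  if (separation < 0) stop_input("separation must be >= 0")
  p <- config$n_channels
  k <- config$n_true_synergies
  labs <- class_labels(config)
  n_motion <- config$n_classes - 1L
  L <- round(config$trial_duration * config$sample_rate)

  with_seed(child_seed(config$seed, 101L), {
    # Each synergy loads dominantly on its own subset of channels
    # (muscle groups), dealt round-robin, plus a small diffuse
    # component — mimicking the sparse co-activation patterns seen in
    # physiological synergies and keeping the basis well-conditioned.
    basis <- matrix(0.05 + 0.15 * runif(p * k), p, k)
    deal <- sample(p)
    for (j in seq_along(deal)) {
      s <- ((j - 1L) %% k) + 1L
      basis[deal[j], s] <- 0.7 + 0.6 * runif(1)
    }
    basis <- sweep(basis, 2L, sqrt(colSums(basis^2)), "/")

    # Per-class synergy weights: a shared base pattern plus a
    # class-specific direction whose strength grows with `separation`.
    # Directions are spread in the non-negative orthant: the first k
    # classes take the coordinate axes, the next the uniform mixture,
    # any further classes random non-negative unit vectors.
    base_w <- 0.2 + 0.3 * abs(rnorm(k))
    weights <- matrix(0, n_motion, k)
    for (c in seq_len(n_motion)) {
      if (c <= k) {
        d <- rep(0, k); d[c] <- 1
      } else if (c == k + 1L) {
        d <- rep(1 / sqrt(k), k)
      } else {
        d <- abs(rnorm(k)); d <- d / sqrt(sum(d^2))
      }
      w <- base_w + separation * d * (0.75 + 0.5 * runif(1))
      weights[c, ] <- w / sqrt(sum(w^2))
    }

    # Per-synergy time courses: a tapered-cosine (Tukey) plateau
    # spanning the trial — the subject moves out of rest, holds the
    # pose, and releases, so activation rises, sustains and falls —
    # mixed with a narrower raised-cosine (Hann) bump staggered across
    # the trial (sequenced recruitment, which makes the planted
    # activation genuinely k-dimensional in time rather than k
    # rescaled copies of one time course).
    tt <- seq(0, 1, length.out = L)
    taper <- 0.2
    wide <- ifelse(tt < taper, 0.5 * (1 - cos(pi * tt / taper)),
                   ifelse(tt > 1 - taper,
                          0.5 * (1 - cos(pi * (1 - tt) / taper)), 1))
    centres <- if (k == 1L) 0.5 else 0.25 + 0.5 * (seq_len(k) - 1) / (k - 1)
    width <- 0.5
    bumps <- matrix(0, k, L)
    for (s in seq_len(k)) {
      u <- (tt - centres[s]) / width + 0.5
      stag <- ifelse(u > 0 & u < 1, 0.5 * (1 - cos(2 * pi * u)), 0)
      bumps[s, ] <- 0.55 * wide + 0.45 * stag
    }
    profiles <- vector("list", config$n_classes)
    names(profiles) <- labs
    for (c in seq_len(n_motion))
      profiles[[c]] <- weights[c, ] * bumps
    profiles[[config$n_classes]] <- matrix(0, k, L)  # rest: silent

    structure(list(basis = basis,
                   class_activation_profiles = profiles,
                   class_labels = labs),
              class = "ground_truth")
  })
}

#' Generate a synthetic EMG session
#'
#' Lays out a full training or testing phase following the session
#' protocol: labeled trials of `trial_duration` seconds separated by
#' `rest_duration` seconds of baseline. Each trial's noise-free signal is
#' `basis %*% (scale * activation_profile)`; the per-repetition scale is
#' `1 + rep_variability * z` and zero-mean Gaussian noise of sd
#' `noise_sd` is added to every sample (rest periods contain baseline
#' noise only). In the training phase every class (including rest)
#' appears `reps_train` times in a fixed block-randomized order; in the
#' testing phase each motion class appears `reps_test` times in a seeded
#' random order, emulating randomized instruction sequences.
#'
#' @param config a [synth_config()].
#' @param truth a [make_ground_truth()] result consistent with `config`.
#' @param phase `"training"` or `"testing"`.
#' @return An `emg_session`: list with `signal` (`n_channels x samples`
#'   matrix of raw signed values), `sample_rate`, `trials` (data.frame
#'   with `start`, `end` half-open 1-based sample indices, `class`,
#'   `rep`) and `phase`.
#' @export
generate_session <- function(config, truth, phase = c("training", "testing")) {
  stopifnot(inherits(config, "synth_config"), inherits(truth, "ground_truth"))
  phase <- match.arg(phase)
  p <- config$n_channels
  k <- config$n_true_synergies
  if (nrow(truth$basis) != p || ncol(truth$basis) != k)
    stop_input("ground truth dimensions inconsistent with config")
  L <- round(config$trial_duration * config$sample_rate)
  if (any(vapply(truth$class_activation_profiles, ncol, 1L) != L))
    stop_input("activation profile length inconsistent with config")
  G <- round(config$rest_duration * config$sample_rate)
  labs <- truth$class_labels
  n_motion <- config$n_classes - 1L

  seed <- child_seed(config$seed, if (phase == "training") 211L else 223L)
  with_seed(seed, {
    if (phase == "training") {
      order_cls <- rep(seq_len(config$n_classes), times = config$reps_train)
      order_cls <- sample(order_cls)                 # shuffled instruction order
      reps_per <- config$reps_train
    } else {
      order_cls <- rep(seq_len(n_motion), times = config$reps_test)
      order_cls <- sample(order_cls)                 # randomized test sequence
      reps_per <- config$reps_test
    }
    n_trials <- length(order_cls)
    total <- G + n_trials * (L + G)
    sig <- matrix(rnorm(p * total, sd = config$noise_sd), p, total)

    starts <- ends <- integer(n_trials)
    rep_counter <- integer(config$n_classes)
    pos <- G
    for (i in seq_len(n_trials)) {
      ci <- order_cls[i]
      rep_counter[ci] <- rep_counter[ci] + 1L
      scale <- max(0, 1 + config$rep_variability * rnorm(1))
      clean <- truth$basis %*% (scale * truth$class_activation_profiles[[ci]])
      idx <- (pos + 1L):(pos + L)
      sig[, idx] <- sig[, idx] + clean
      starts[i] <- pos + 1L
      ends[i] <- pos + L + 1L    # half-open
      pos <- pos + L + G
    }
    trials <- data.frame(start = starts, end = ends,
                         class = labs[order_cls],
                         rep = unlist(lapply(seq_len(n_trials), function(i) {
                           sum(order_cls[seq_len(i)] == order_cls[i])
                         })),
                         stringsAsFactors = FALSE)
    structure(list(signal = sig, sample_rate = config$sample_rate,
                   trials = trials, phase = phase,
                   class_labels = labs),
              class = "emg_session")
  })
}

#' @export
print.emg_session <- function(x, ...) {
  cat(sprintf("<emg_session> %s phase: %d channels, %d samples @ %g Hz, %d trials\n",
              x$phase, nrow(x$signal), ncol(x$signal), x$sample_rate,
              nrow(x$trials)))
  print(table(x$trials$class))
  invisible(x)
}

#' Extract the signal of one trial
#'
#' @param session an `emg_session` (or envelope session).
#' @param i trial row index in `session$trials`.
#' @return `n_channels x trial_samples` matrix.
#' @export
trial_signal <- function(session, i) {
  tr <- session$trials[i, ]
  session$signal[, tr$start:(tr$end - 1L), drop = FALSE]
}

#' Write / read a session in a plain columnar format
#'
#' Two tables: one of samples (`sample`, `ch1..chP`) and one of trials
#' (`start`, `end`, `class`, `rep`, `phase`). `format = "csv"` writes
#' human-readable text (round-trip exact to full double precision via
#' 17 significant digits); `format = "rds"` writes a lossless binary
#' container.
#'
#' @param session an `emg_session`.
#' @param path base path; `_samples.csv` / `_trials.csv` suffixes are
#'   appended for CSV, `.rds` for the binary container.
#' @param format `"csv"` or `"rds"`.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, format = c("csv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(session, paste0(path, ".rds"))
    return(invisible(path))
  }
  samples <- data.frame(sample = seq_len(ncol(session$signal)),
                        t(session$signal))
  names(samples) <- c("sample", paste0("ch", seq_len(nrow(session$signal))))
  tr <- session$trials
  tr$phase <- session$phase
  hdr <- sprintf("# sample_rate=%.17g class_labels=%s", session$sample_rate,
                 paste(session$class_labels, collapse = ","))
  f <- paste0(path, "_samples.csv")
  writeLines(hdr, f)
  suppressWarnings(write.table(format(samples, digits = 17, trim = TRUE,
                                      scientific = TRUE),
                               f, sep = ",", row.names = FALSE,
                               quote = FALSE, append = TRUE))
  write.csv(tr, paste0(path, "_trials.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path, format = c("csv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") return(readRDS(paste0(path, ".rds")))
  f <- paste0(path, "_samples.csv")
  hdr <- readLines(f, n = 1L)
  sr <- as.numeric(sub(".*sample_rate=([^ ]+).*", "\\1", hdr))
  labs <- strsplit(sub(".*class_labels=([^ ]+)$", "\\1", hdr), ",")[[1]]
  samples <- read.csv(f, skip = 1L)
  tr <- read.csv(paste0(path, "_trials.csv"), stringsAsFactors = FALSE)
  phase <- tr$phase[1]
  tr$phase <- NULL
  structure(list(signal = t(as.matrix(samples[, -1, drop = FALSE])),
                 sample_rate = sr, trials = tr, phase = phase,
                 class_labels = labs),
            class = "emg_session")
}
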