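#' Non-negative matrix factorization by alternating non-negative least
#' squares
#'
#' Factorizes a non-negative matrix `X` (channels x samples) as
#' `X = A Y + E` with `A >= 0` (`p x k` synergy basis) and `Y >= 0`
#' (`k x q` activation coefficients), minimizing the Frobenius residual
#' `||X - A Y||_F^2` by exact alternating non-negative least squares:
#' each half-step solves its subproblem to optimality (grouped
#' active-set solver with a tiny ridge for conditioning), so the
#' objective is non-increasing across iterations. Basis columns are
#' rescaled to unit Euclidean norm after every sweep (a pure
#' reparameterization that leaves `A Y` unchanged).
#'
#' @param X non-negative matrix, channels x samples.
#' @param k number of synergies, `1 <= k <= nrow(X)`.
#' @param max_iter maximum number of alternating sweeps.
#' @param tol stop when the relative objective decrease falls below this.
#' @param seed seed for the random (uniform) initialization of `A`.
#' @param init_basis optional `p x k'` non-negative matrix (`k' <= k`)
#'   used to warm-start the first `k'` basis columns.
#' @param ridge small ridge added to the normal equations of each
#'   subproblem for numerical conditioning.
#' @return List with `basis` (`p x k`), `coefficients` (`k x q`),
#'   `residual_fro` (Frobenius norm of the residual), `objective`
#'   (per-iteration squared-residual history) and `iterations`.
#' @export
nmf_fit <- function(X, k, max_iter = 100L, tol = 1e-6, seed = 1L,
                    init_basis = NULL, ridge = 1e-12) {
  X <- as.matrix(X)
  if (any(X < 0)) stop_input("nmf_fit: input must be non-negative")
  p <- nrow(X)
  if (k < 1L || k > p) stop_input("nmf_fit: need 1 <= k <= nrow(X)")
  A <- with_seed(seed, matrix(runif(p * k, 0.1, 1), p, k))
  if (!is.null(init_basis)) {
    kw <- ncol(init_basis)
    if (nrow(init_basis) != p || kw > k || any(init_basis < 0))
      stop_input("nmf_fit: invalid init_basis")
    A[, seq_len(kw)] <- init_basis
  }
  obj <- numeric(0)
  Y <- NULL
  for (it in seq_len(max_iter)) {
    Y <- nnls_multi(A, X, ridge = ridge)
    A <- t(nnls_multi(t(Y), t(X), ridge = ridge))
    # guard against dead synergies (all-zero columns make the next
    # subproblem singular beyond the ridge)
    dead <- colSums(A) == 0
    if (any(dead))
      A[, dead] <- matrix(with_seed(child_seed(seed, it), runif(p * sum(dead), 0.1, 1)),
                          p, sum(dead))
    sse <- sum((X - A %*% Y)^2)
    obj <- c(obj, sse)
    if (it > 1L) {
      rel <- (obj[it - 1L] - sse) / max(obj[it - 1L], .Machine$double.eps)
      if (rel >= 0 && rel < tol) break
    }
  }
  nrm <- sqrt(colSums(A^2))
  nrm[nrm == 0] <- 1
  A <- sweep(A, 2L, nrm, "/")
  Y <- sweep(Y, 1L, nrm, "*")
  list(basis = A, coefficients = Y,
       residual_fro = sqrt(obj[length(obj)]),
       objective = obj, iterations = length(obj))
}

# Explained variance of a fit: 1 - SSE / SST with SST uncentered
# (||X||_F^2) by default; centered subtracts the per-channel mean.
explained_variance <- function(X, sse, centered = FALSE) {
  sst <- if (centered) sum(sweep(X, 1L, rowMeans(X))^2) else sum(X^2)
  1 - sse / sst
}

#' Choose the number of synergies from the explained-variance profile
#'
#' Fits the factorization for every candidate dimension `k = 1..p` and
#' computes the cumulative explained variance
#' `EV(k) = 1 - ||X - A Y||_F^2 / SST`. Each `k` is warm-started from
#' the `k - 1` solution (plus a fresh random fit, keeping the better),
#' which makes the profile non-decreasing. The chosen dimension is the
#' smallest `k` satisfying both criteria: `EV(k) >= variance_threshold`
#' (at least 90 % of the signal variance captured, by default) and
#' `EV(k+1) - EV(k) < slope_threshold` (the profile has flattened:
#' adding a synergy buys less than 5 % more variance; `EV(p+1)` is
#' taken as 1).
#'
#' @param X non-negative matrix, channels x samples.
#' @param variance_threshold minimum cumulative explained variance.
#' @param slope_threshold maximum gain from one additional synergy.
#' @param seed seed for the factorization initializations.
#' @param max_iter,tol passed to [nmf_fit()].
#' @param centered use mean-centered total sum of squares (default
#'   uncentered, the convention for non-negative data).
#' @return List with `chosen_k`, `explained_variance_profile` (length
#'   `p`), and `fits` (the per-k fit objects).
#' @export
select_num_synergies <- function(X, variance_threshold = 0.90,
                                 slope_threshold = 0.05, seed = 1L,
                                 max_iter = 100L, tol = 1e-6,
                                 centered = FALSE) {
  X <- as.matrix(X)
  if (variance_threshold <= 0 || variance_threshold >= 1 ||
      slope_threshold <= 0 || slope_threshold >= 1)
    stop_input("thresholds must lie in (0, 1)")
  p <- nrow(X)
  fits <- vector("list", p)
  ev <- numeric(p)
  for (k in seq_len(p)) {
    fit <- nmf_fit(X, k, max_iter = max_iter, tol = tol,
                   seed = child_seed(seed, k))
    if (k > 1L) {
      warm <- nmf_fit(X, k, max_iter = max_iter, tol = tol,
                      seed = child_seed(seed, 100L + k),
                      init_basis = fits[[k - 1L]]$basis)
      if (warm$residual_fro < fit$residual_fro) fit <- warm
    }
    fits[[k]] <- fit
    ev[k] <- explained_variance(X, fit$residual_fro^2, centered = centered)
  }
  ev_ext <- c(ev, 1)
  ok <- ev >= variance_threshold & (ev_ext[-1L] - ev) < slope_threshold
  chosen_k <- if (any(ok)) which(ok)[1L] else p
  list(chosen_k = chosen_k, explained_variance_profile = ev, fits = fits)
}

#' Fit a muscle-synergy model on a training session
#'
#' Concatenates the envelope samples of the training motion trials
#' (rest trials excluded by default: rest carries no synergy
#' information, though the switch is provided), selects the number of
#' synergies by the explained-variance criteria (unless `k` is given),
#' and returns the basis together with its real-time projection
#' operator — the Moore-Penrose pseudoinverse of the rectangular basis,
#' i.e. the least-squares decoder of synergy activations from an
#' envelope sample.
#'
#' @param session an envelope `emg_session` (training phase).
#' @param k fixed number of synergies; `NULL` selects automatically.
#' @param variance_threshold,slope_threshold selection criteria, see
#'   [select_num_synergies()].
#' @param include_rest include rest-trial samples in the factorization.
#' @param decimation keep every `decimation`-th envelope sample for the
#'   factorization. The envelope is low-pass filtered at 10 Hz, so at a
#'   1 kHz acquisition rate a factor of 10 (effective 100 Hz) retains
#'   the full envelope bandwidth while cutting the factorization cost
#'   tenfold; the fitted basis is unaffected.
#' @param seed,max_iter,tol factorization controls.
#' @return A `synergy_model`: `basis`, `projector` (`k x p`),
#'   `explained_variance_profile`, `chosen_k`, `residual_r2` (residual
#'   variance fraction of the retained fit), `seed`.
#' @export
fit_synergy_model <- function(session, k = NULL, variance_threshold = 0.90,
                              slope_threshold = 0.05, include_rest = FALSE,
                              decimation = 10L, seed = 1L, max_iter = 100L,
                              tol = 1e-6) {
  keep <- if (include_rest) seq_len(nrow(session$trials)) else
    which(session$trials$class != "rest")
  X <- do.call(cbind, lapply(keep, function(i) trial_signal(session, i)))
  if (decimation > 1L)
    X <- X[, seq.int(1L, ncol(X), by = decimation), drop = FALSE]
  sel <- NULL
  if (is.null(k)) {
    sel <- select_num_synergies(X, variance_threshold, slope_threshold,
                                seed = seed, max_iter = max_iter, tol = tol)
    k <- sel$chosen_k
    fit <- sel$fits[[k]]
    profile <- sel$explained_variance_profile
  } else {
    fit <- nmf_fit(X, k, max_iter = max_iter, tol = tol, seed = seed)
    profile <- explained_variance(X, fit$residual_fro^2)
  }
  structure(list(basis = fit$basis,
                 projector = MASS::ginv(fit$basis),
                 explained_variance_profile = profile,
                 chosen_k = k,
                 residual_r2 = fit$residual_fro^2 / sum(X^2),
                 seed = seed),
            class = "synergy_model")
}

#' @export
print.synergy_model <- function(x, ...) {
  cat(sprintf("<synergy_model> %d synergies over %d channels; residual R2 = %.2f %%\n",
              x$chosen_k, nrow(x$basis), 100 * x$residual_r2))
  invisible(x)
}

#' Project envelope samples into synergy space
#'
#' Real-time decoding of synergy activations: left-multiplication by
#' the Moore-Penrose pseudoinverse of the basis, `Y = pinv(A) X`,
#' equivalently the least-squares solution of `A y = x` per sample.
#' The output is a plain linear map of the input and is deliberately
#' not clipped, so mild negative coefficients can occur.
#'
#' @param model a `synergy_model`.
#' @param x envelope vector (length p) or matrix (`p x q`).
#' @return Coefficient vector (length k) or matrix (`k x q`).
#' @export
project_online <- function(model, x) {
  if (is.vector(x)) {
    if (length(x) != ncol(model$projector))
      stop_input("project_online: dimension mismatch")
    return(drop(model$projector %*% x))
  }
  if (nrow(x) != ncol(model$projector))
    stop_input("project_online: dimension mismatch")
  model$projector %*% x
}

#' Extract sliding-window synergy features
#'
#' Projects envelope samples onto the synergy space and summarizes each
#' sliding window by its mean coefficient vector (the natural
#' MAV-analog for non-negative activations; by linearity this equals
#' projecting the window-mean envelope). Feature dimension is the
#' number of synergies. With `summary = "passthrough"` every sample's
#' coefficient vector is emitted instead (one column per sample).
#'
#' @param session an envelope `emg_session`.
#' @param model a fitted `synergy_model`.
#' @param spec a [window_spec()].
#' @param summary `"mean"` (per-window mean coefficients) or
#'   `"passthrough"` (per-sample coefficients).
#' @return A `feature_matrix` with `feature_kind = "synergy"`.
#' @export
extract_synergy_features <- function(session, model, spec = window_spec(),
                                     summary = c("mean", "passthrough")) {
  summary <- match.arg(summary)
  p <- nrow(session$signal)
  if (ncol(model$projector) != p)
    stop_input("extract_synergy_features: channel mismatch")
  kdim <- nrow(model$projector)
  vals <- list(); labs <- list(); ends <- list(); tri <- list()
  for (i in seq_len(nrow(session$trials))) {
    tr <- session$trials[i, ]
    len <- tr$end - tr$start
    seg <- session$signal[, tr$start:(tr$end - 1L), drop = FALSE]
    if (summary == "passthrough") {
      m <- project_online(model, seg)
      st_ends <- tr$start:(tr$end - 1L)
    } else {
      st <- window_starts(len, spec)
      if (length(st) == 0L) {
        warning("trial ", i, " shorter than window; skipped")
        next
      }
      means <- vapply(st, function(s)
        rowMeans(seg[, s:(s + spec$window - 1L), drop = FALSE]),
        numeric(p))
      m <- project_online(model, matrix(means, nrow = p))
      st_ends <- tr$start - 1L + st + spec$window - 1L
    }
    m <- matrix(m, nrow = kdim)
    vals[[length(vals) + 1L]] <- m
    labs[[length(labs) + 1L]] <- rep(tr$class, ncol(m))
    ends[[length(ends) + 1L]] <- st_ends
    tri[[length(tri) + 1L]] <- rep(i, ncol(m))
  }
  if (length(vals) == 0L) stop_input("no trial long enough for one window")
  structure(list(values = do.call(cbind, vals),
                 labels = unlist(labs),
                 trial = unlist(tri),
                 window_end = unlist(ends),
                 feature_kind = "synergy",
                 feature_names = paste0("syn", seq_len(kdim))),
            class = "feature_matrix")
}

#' Serialize / restore a synergy model
#'
#' @param model a `synergy_model`.
#' @param path file path (RDS container).
#' @return `path` invisibly; `read_synergy_model` returns the model.
#' @export
write_synergy_model <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname write_synergy_model
#' @export
read_synergy_model <- function(path) {
  structure(readRDS(path), class = "synergy_model")
}
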