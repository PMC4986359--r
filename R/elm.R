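#' Extreme learning machine: hidden-layer activation map
#'
#' Applies the model's frozen random hidden layer to a batch of input
#' vectors. The default activation is the triangular basis function
#' `tribas(v) = max(1 - |v|, 0)` applied to the affine pre-activation
#' `v = y . r_j + b_j`; `"rbf"` uses Gaussian radial units
#' `exp(-zeta_j ||y - c_j||^2)` with random centers and widths, and
#' `"sigmoid"` the logistic function of the affine pre-activation.
#'
#' @param model an `elm_model` (hidden parameters drawn at [elm_fit()]
#'   time and frozen).
#' @param inputs matrix, one row per sample (`n x Z`), on the model's
#'   standardized scale (applied internally by [elm_predict()]).
#' @return Activation matrix `H` (`n x n_hidden`).
#' @export
elm_hidden_map <- function(model, inputs) {
  Z <- ncol(model$hidden_weights)
  if (is.null(dim(inputs))) {
    if (length(inputs) != Z) stop_input("elm_hidden_map: input dimension mismatch")
    inputs <- matrix(inputs, 1L)
  }
  if (ncol(inputs) != Z)
    stop_input("elm_hidden_map: input dimension mismatch")
  if (model$activation == "rbf") {
    # ||y - c_j||^2 = ||y||^2 - 2 y.c_j + ||c_j||^2
    d2 <- outer(rowSums(inputs^2), rowSums(model$hidden_weights^2), "+") -
      2 * tcrossprod(inputs, model$hidden_weights)
    return(exp(-sweep(pmax(d2, 0), 2L, model$hidden_biases, "*")))
  }
  v <- tcrossprod(inputs, model$hidden_weights)
  v <- sweep(v, 2L, model$hidden_biases, "+")
  switch(model$activation,
         tribas = pmax(1 - abs(v), 0),
         sigmoid = 1 / (1 + exp(-v)))
}

# One-hot target matrix (n x m) in the model's class order.
one_hot <- function(labels, class_order) {
  idx <- match(labels, class_order)
  if (anyNA(idx)) stop_input("labels outside class order")
  o <- matrix(0, length(labels), length(class_order))
  o[cbind(seq_along(labels), idx)] <- 1
  o
}

# Ridge-regularized closed-form output weights:
# w = (H'H + lambda I)^{-1} H' o, solved by Cholesky with a
# pseudoinverse fallback for (numerically) singular systems.
solve_output_weights <- function(H, O, lambda) {
  G <- crossprod(H)
  diag(G) <- diag(G) + lambda
  ok <- TRUE
  ch <- tryCatch(chol(G), error = function(e) { ok <<- FALSE; NULL })
  if (ok) return(chol2inv(ch) %*% crossprod(H, O))
  message("elm_fit: singular normal equations; pseudoinverse fallback")
  MASS::ginv(G) %*% crossprod(H, O)
}

#' Train an extreme learning machine classifier
#'
#' Single-hidden-layer feed-forward network with random frozen hidden
#' parameters: hidden weights and biases are drawn i.i.d. uniform on
#' \[-1, 1\] (the convention of the original ELM literature) and never
#' updated; only the linear output layer is learned, in closed form, as
#' the ridge-regression solution
#' `w = (H'H + lambda I)^{-1} H' o`
#' against one-hot class targets `o`. Since the triangular activation
#' has support only on pre-activations in (-1, 1), inputs are z-scored
#' with training-set statistics stored in the model and re-applied at
#' prediction.
#'
#' @param features a `feature_matrix`, or a plain matrix (`n x Z`) with
#'   `labels` supplied.
#' @param n_hidden number of hidden neurons.
#' @param lambda ridge parameter (the `C`-parameterized form of the
#'   same problem corresponds to `lambda = 1/C`).
#' @param seed seed for the random hidden parameters.
#' @param activation hidden activation: `"tribas"` (default), `"rbf"`,
#'   or `"sigmoid"`.
#' @param labels class labels, one per row/column of `features`, when
#'   `features` is a plain matrix.
#' @param standardize z-score inputs with training statistics.
#' @return An `elm_model` with everything needed for stateless
#'   prediction: hidden parameters, standardization statistics, output
#'   weights, class order and seed.
#' @export
elm_fit <- function(features, n_hidden = 500L, lambda = 1e-3, seed = 1L,
                    activation = c("tribas", "rbf", "sigmoid"),
                    labels = NULL, standardize = TRUE) {
  activation <- match.arg(activation)
  if (inherits(features, "feature_matrix")) {
    labels <- features$labels
    X <- t(features$values)
  } else {
    X <- as.matrix(features)
  }
  if (is.null(labels) || length(labels) != nrow(X))
    stop_input("elm_fit: need one label per sample")
  class_order <- sort(unique(labels))
  if (length(class_order) < 2L) stop_input("elm_fit: need >= 2 classes")
  if (n_hidden < 1L) stop_input("elm_fit: n_hidden must be >= 1")
  if (lambda < 0) stop_input("elm_fit: lambda must be >= 0")

  mu <- if (standardize) colMeans(X) else rep(0, ncol(X))
  sdv <- if (standardize) apply(X, 2L, sd) else rep(1, ncol(X))
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")

  Z <- ncol(X)
  pars <- with_seed(child_seed(seed, 17L), {
    W <- matrix(runif(n_hidden * Z, -1, 1), n_hidden, Z)
    b <- if (activation == "rbf") runif(n_hidden, 0.05, 1) else
      runif(n_hidden, -1, 1)
    list(W = W, b = b)
  })
  model <- structure(list(hidden_weights = pars$W, hidden_biases = pars$b,
                          activation = activation, lambda = lambda,
                          center = mu, scale = sdv,
                          class_order = class_order, seed = seed),
                     class = "elm_model")
  H <- elm_hidden_map(model, Xs)
  model$output_weights <- solve_output_weights(H, one_hot(labels, class_order),
                                               lambda)
  model
}

#' @export
print.elm_model <- function(x, ...) {
  cat(sprintf("<elm_model> %d hidden '%s' neurons, %d inputs, %d classes, lambda=%g\n",
              nrow(x$hidden_weights), x$activation, ncol(x$hidden_weights),
              length(x$class_order), x$lambda))
  invisible(x)
}

#' Predict classes with a trained ELM
#'
#' Scores are the network outputs `H w` per class; the predicted class
#' is the argmax over output nodes, ties broken deterministically
#' towards the lowest class index. When the model has a single output
#' node (binary case trained on +/-1 targets) the sign decision is
#' used instead.
#'
#' @param model a fitted `elm_model`.
#' @param features a `feature_matrix` or plain matrix (`n x Z`).
#' @return List with `class` (character vector, length n) and `scores`
#'   (`n x m`).
#' @export
elm_predict <- function(model, features) {
  if (is.null(model$output_weights)) stop_input("elm_predict: model not fitted")
  Z <- ncol(model$hidden_weights)
  X <- if (inherits(features, "feature_matrix")) t(features$values)
       else if (is.null(dim(features))) matrix(features, 1L)
       else as.matrix(features)
  if (ncol(X) != Z) stop_input("elm_predict: input dimension mismatch")
  Xs <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  S <- elm_hidden_map(model, Xs) %*% model$output_weights
  if (length(model$class_order) == 1L) {
    cls <- ifelse(drop(S) >= 0, model$class_order, paste0("not_", model$class_order))
    return(list(class = cls, scores = S))
  }
  pick <- max.col(S, ties.method = "first")
  list(class = model$class_order[pick], scores = S)
}

#' Select the hidden-layer size by stratified cross-validation
#'
#' A small k-fold (default 2-fold) cross-validation over a grid of
#' hidden-layer sizes, guarding against over-fitting: folds are
#' stratified by class, mean held-out accuracy is computed per grid
#' value and the argmax is returned (ties towards the smaller network).
#' The default grid spans the sizes typical for this decoding problem.
#'
#' @param features a `feature_matrix` or plain matrix with `labels`.
#' @param grid candidate hidden-layer sizes.
#' @param lambda ridge parameter used in every fit.
#' @param folds number of folds (>= 2).
#' @param seed controls fold assignment and the per-fit hidden layers.
#' @param labels labels when `features` is a plain matrix.
#' @param activation hidden activation passed to [elm_fit()].
#' @return List with `best_n_hidden` and `cv_accuracy` (named vector,
#'   percent per grid value).
#' @export
elm_cv_select_hidden <- function(features, grid = c(500L, 1000L, 2000L, 3500L, 5000L),
                                 lambda = 1e-3, folds = 2L, seed = 1L,
                                 labels = NULL,
                                 activation = "tribas") {
  if (length(grid) == 0L) stop_input("empty grid")
  if (folds < 2L) stop_input("folds must be >= 2")
  if (inherits(features, "feature_matrix")) {
    labels <- features$labels
    X <- t(features$values)
  } else X <- as.matrix(features)
  fold_id <- with_seed(child_seed(seed, 29L), {
    id <- integer(nrow(X))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < folds)
        stop_input("class ", cl, " has fewer samples than folds")
      id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    id
  })
  acc <- matrix(NA_real_, length(grid), folds)
  for (g in seq_along(grid)) {
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      m <- elm_fit(X[tr, , drop = FALSE], n_hidden = grid[g], lambda = lambda,
                   seed = child_seed(seed, 1000L + f), labels = labels[tr],
                   activation = activation)
      pr <- elm_predict(m, X[!tr, , drop = FALSE])
      acc[g, f] <- mean(pr$class == labels[!tr]) * 100
    }
  }
  cv <- rowMeans(acc)
  names(cv) <- as.character(grid)
  list(best_n_hidden = grid[which.max(cv)], cv_accuracy = cv)
}

#' Serialize / restore an ELM model
#'
#' The file stores every random parameter, the standardization
#' statistics, output weights, class order and seed, so a reloaded
#' model gives bit-identical predictions.
#'
#' @param model an `elm_model`.
#' @param path file path (RDS container).
#' @return `path` invisibly; `read_elm_model` returns the model.
#' @export
write_elm_model <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname write_elm_model
#' @export
read_elm_model <- function(path) {
  structure(readRDS(path), class = "elm_model")
}
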