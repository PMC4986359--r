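# Non-negative least squares for many right-hand sides, via grouped
# active sets (columns sharing a passive-set pattern are solved in one
# dense solve). Used as the inner solver of the alternating NMF; the
# design dimension here is the number of channels / synergies, so the
# k x k subsystems are tiny while the number of right-hand sides (data
# samples) is large.

# Solve the normal equations restricted to each column's passive set.
cssls <- function(CtC, CtB, P = NULL) {
  if (is.null(P)) return(solve(CtC, CtB))
  K <- matrix(0, nrow(CtB), ncol(CtB))
  l <- nrow(P)
  codes <- as.vector(crossprod(2^(seq_len(l) - 1), P))
  for (code in unique(codes)) {
    cols <- which(codes == code)
    pset <- which(P[, cols[1L]])
    if (length(pset) == 0L) next
    K[pset, cols] <- solve(CtC[pset, pset, drop = FALSE],
                           CtB[pset, cols, drop = FALSE])
  }
  K
}

# min_{K >= 0} ||C K - B||_F^2 (+ ridge ||K||^2), columns independent.
nnls_multi <- function(C, B, ridge = 1e-12) {
  l <- ncol(C)
  CtC <- crossprod(C) + diag(ridge, l)
  CtB <- crossprod(C, B)
  K <- cssls(CtC, CtB)
  P <- K > 0
  K[!P] <- 0
  active <- which(colSums(!P) > 0L)   # columns whose unconstrained solve broke
  iter <- 0L
  maxit <- 10L * l * max(1L, l)
  while (length(active) > 0L && iter < maxit) {
    iter <- iter + 1L
    Ka <- cssls(CtC, CtB[, active, drop = FALSE], P[, active, drop = FALSE])
    neg <- Ka < -1e-12 & P[, active, drop = FALSE]
    bad <- colSums(neg) > 0L
    if (any(bad)) {
      # infeasible passive variables: move them to the active set
      sub <- P[, active, drop = FALSE]
      sub[neg] <- FALSE
      P[, active] <- sub
      next
    }
    Ka[Ka < 0] <- 0
    # optimality: any zeroed variable with positive descent gradient?
    W <- CtB[, active, drop = FALSE] - CtC %*% Ka
    W[P[, active, drop = FALSE]] <- -Inf
    gains <- apply(W, 2L, max)
    K[, active] <- Ka
    notopt <- which(gains > 1e-10)
    if (length(notopt) == 0L) break
    for (j in notopt) {
      P[which.max(W[, j]), active[j]] <- TRUE
    }
    active <- active[notopt]
  }
  pmax(K, 0)
}
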