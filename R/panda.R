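#' Row/column z-score normalization of a network matrix
#'
#' Standardizes a matrix the way the message-passing core expects its three
#' input networks: each entry becomes `(z_row + z_col) / sqrt(2)`, where
#' `z_row` z-scores within the entry's row and `z_col` within its column
#' (sample, n - 1, standard deviations). A zero-variance row or column
#' contributes 0 and the surviving component is still scaled by `1/sqrt(2)`;
#' entries degenerate in both directions come out 0. The transform is
#' invariant to affine maps `a*M + b` with `a > 0`.
#'
#' @param M Numeric matrix, all entries finite.
#' @return Matrix of the same shape, dimnames preserved.
#' @export
normalize_network <- function(M) {
  M <- as.matrix(M)
  if (length(M) == 0) stop("empty matrix")
  if (!all(is.finite(M))) stop("non-finite entries in matrix")
  zr <- .zscore_rows(M)
  zc <- t(.zscore_rows(t(M)))
  (zr + zc) / sqrt(2)
}

# z-score each row with sample sd; zero-variance rows map to 0.
.zscore_rows <- function(M) {
  mu <- rowMeans(M)
  sdv <- sqrt(row_var(M))
  z <- (M - mu) / sdv
  bad <- !is.finite(sdv) | sdv == 0
  if (any(bad)) z[bad, ] <- 0
  z
}

#' Continuous Tanimoto similarity between matrix rows and columns
#'
#' For `X` (n x k) and `Y` (k x m) returns the n x m matrix
#' `S_ij = d_ij / sqrt(||X_i.||^2 + ||Y_.j||^2 - |d_ij|)` with
#' `d_ij = sum_k X_ik Y_kj`; entries with a zero denominator are set to 0.
#' This is the similarity kernel used to derive the responsibility and
#' availability messages.
#'
#' @param X,Y Numeric matrices with matching inner dimension.
#' @return n x m numeric matrix.
#' @export
tanimoto <- function(X, Y) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (ncol(X) != nrow(Y)) stop("inner dimensions do not agree")
  if (!all(is.finite(X)) || !all(is.finite(Y))) stop("non-finite input")
  d <- X %*% Y
  denom2 <- outer(rowSums(X^2), colSums(Y^2), `+`) - abs(d)
  s <- d / sqrt(denom2)
  s[!is.finite(s)] <- 0
  s
}

#' Gene-gene co-expression matrix
#'
#' Pearson correlation across samples. Zero-variance genes get 0 off the
#' diagonal and 1 on it.
#'
#' @param expr Gene x sample numeric matrix with at least 3 samples.
#' @return Gene x gene correlation matrix.
#' @export
coexpression <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) stop("need at least 3 samples for co-expression")
  cc <- suppressWarnings(stats::cor(t(expr)))
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  cc
}

# Diagonal refill used when the TF-TF and gene-gene networks are re-estimated
# from W: the raw Tanimoto self-similarity dominates, so the diagonal is
# replaced by (sd of the row's off-diagonal entries) * dim * exp(2*alpha*step).
# step is 0-based (0 on the first iteration). Matrices smaller than 3x3 have
# no defined off-diagonal sd; their diagonal is set to 0.
.update_diagonal <- function(M, alpha, step) {
  n <- ncol(M)
  if (n < 3L) {
    diag(M) <- 0
    return(M)
  }
  dg <- diag(M)
  mu_off <- (rowSums(M) - dg) / (n - 1)
  ss_off <- rowSums(M^2) - dg^2
  var_off <- pmax(0, (ss_off - (n - 1) * mu_off^2) / (n - 2))
  diag(M) <- sqrt(var_off) * n * exp(2 * alpha * step)
  M
}

#' Message-passing regulatory network reconstruction
#'
#' Refines a binary TF x gene motif prior into a weighted regulatory network
#' by iteratively passing messages between three evidence layers: the
#' regulatory network `W` (TF x gene), TF-TF cooperativity `P`, and gene-gene
#' co-regulation `C`. All three inputs are first standardized with
#' [normalize_network()]. Each iteration computes the responsibility
#' `R = tanimoto(P, W)` and availability `A = tanimoto(W, C)`, moves `W`
#' toward their average with learning rate `alpha`, then re-estimates `P` and
#' `C` from the updated `W` (with the diagonal refill rule) and moves them the
#' same way. Iteration stops when the mean absolute change in `W` drops to
#' `tol` or below, or at `max_iter`. Final edge scores are on a Z-score-like
#' scale and may be negative; downstream callers filter on sign.
#'
#' @param prior TF x gene numeric matrix (typically 0/1 motif prior) with
#'   dimnames naming TFs and genes.
#' @param ppi TF x TF symmetric numeric matrix (0/1 interactions, diagonal 1).
#' @param coexpr Gene x gene co-expression matrix, e.g. from [coexpression()].
#' @param alpha Learning rate in (0, 1].
#' @param tol Convergence tolerance on the mean absolute update of `W`.
#'   `tol = Inf` returns the normalized prior untouched (0 iterations).
#' @param max_iter Iteration cap; hitting it yields a warning, not an error.
#' @return An object of class `regulatory_network`: list with `tfs`, `genes`,
#'   `edge_scores` (final W), `converged`, `iterations`, `hamming_trace`.
#' @export
panda <- function(prior, ppi, coexpr, alpha = 0.1, tol = 1e-3, max_iter = 200L) {
  prior <- as.matrix(prior)
  ppi <- as.matrix(ppi)
  coexpr <- as.matrix(coexpr)
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (nrow(ppi) != nrow(prior) || ncol(ppi) != nrow(prior))
    stop("ppi must be TF x TF matching the prior's rows")
  if (nrow(coexpr) != ncol(prior) || ncol(coexpr) != ncol(prior))
    stop("coexpr must be gene x gene matching the prior's columns")

  W <- normalize_network(prior)
  P <- normalize_network(ppi)
  C <- normalize_network(coexpr)

  step <- 0L
  hamming <- Inf
  trace <- numeric(0)
  while (hamming > tol && step < max_iter) {
    W_old <- W
    R <- tanimoto(P, W)
    A <- tanimoto(W, C)
    W <- (1 - alpha) * W + alpha * (R + A) / 2
    P_hat <- .update_diagonal(tanimoto(W, t(W)), alpha, step)
    P <- (1 - alpha) * P + alpha * P_hat
    C_hat <- .update_diagonal(tanimoto(t(W), W), alpha, step)
    C <- (1 - alpha) * C + alpha * C_hat
    step <- step + 1L
    hamming <- mean(abs(W - W_old))
    trace <- c(trace, hamming)
  }
  converged <- hamming <= tol
  if (!converged)
    warning("message passing did not converge in ", max_iter,
            " iterations (last update ", signif(hamming, 3), ")")
  structure(
    list(tfs = rownames(prior), genes = colnames(prior), edge_scores = W,
         converged = converged, iterations = step, hamming_trace = trace),
    class = "regulatory_network"
  )
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("Regulatory network:", length(x$tfs), "TFs x", length(x$genes),
      "genes;", x$iterations, "iterations;",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}
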