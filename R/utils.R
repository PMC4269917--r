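# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so generators are bit-reproducible without clobbering
#' the caller's random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    genv <- globalenv()
    if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      old <- get(".Random.seed", envir = genv)
      on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = genv, inherits = FALSE))
          rm(".Random.seed", envir = genv),
        add = TRUE
      )
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Deterministic derived seed for sub-computations
#'
#' Maps a base seed and an index to a distinct integer seed inside the
#' 32-bit range, so nested generators stay reproducible without sharing a
#' stream.
#' @param seed Base integer seed.
#' @param i Index of the sub-computation.
#' @return Integer seed.
#' @export
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(i) * 7919) %% 2147483587L)
}

# Row-wise sample variance (n - 1 denominator).
row_var <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

#' Row-wise pooled-variance two-sample t-test
#'
#' Classic unpaired t with pooled variance, vectorised over rows. Rows where
#' the pooled standard error is zero get `t = 0, p = 1` when the group means
#' agree (identical constant data) and `t = +/-Inf, p = 0` otherwise.
#'
#' @param x,y Numeric matrices with identical row count; columns are the two
#'   groups' observations.
#' @return A list with `mean_x`, `mean_y`, `diff` (`mean_x - mean_y`),
#'   `t_stat`, `df`, `p_value`.
#' @keywords internal
row_pooled_t <- function(x, y) {
  stopifnot(nrow(x) == nrow(y))
  n1 <- ncol(x)
  n2 <- ncol(y)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 columns")
  m1 <- rowMeans(x)
  m2 <- rowMeans(y)
  sp2 <- ((n1 - 1) * row_var(x) + (n2 - 1) * row_var(y)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  d <- m1 - m2
  t_stat <- d / se
  degen <- se == 0
  t_stat[degen & d == 0] <- 0
  p <- 2 * stats::pt(-abs(t_stat), df = n1 + n2 - 2)
  p[degen & d == 0] <- 1
  p[degen & d != 0] <- 0
  list(mean_x = m1, mean_y = m2, diff = d, t_stat = t_stat,
       df = n1 + n2 - 2, p_value = p)
}
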