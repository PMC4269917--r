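#' Marker-gene PCA sex check
#'
#' Runs a principal component analysis of the marker-gene submatrix (samples
#' as observations, gene-centered), splits samples into two clusters on PC1
#' (2-means seeded at the PC1 extremes, so the split is deterministic), and
#' flags every sample whose cluster's majority recorded sex differs from its
#' own recorded sex. With markers emulating Y-chromosome probes the two
#' clusters are the sexes, and flags indicate mislabeling or poor-quality
#' arrays; the study workflow drops flagged subjects before analysis.
#'
#' @param expr Gene x sample matrix containing the marker genes.
#' @param metadata data.frame with `sample_id` and `sex` columns matching
#'   `colnames(expr)`.
#' @param marker_genes Character vector of marker gene ids (>= 2 present).
#' @return List with `scores` (sample x PC matrix, first two PCs),
#'   `cluster` (named integer vector), `flagged` (character vector of sample
#'   ids).
#' @export
sex_check_pca <- function(expr, metadata, marker_genes) {
  present <- intersect(marker_genes, rownames(expr))
  if (length(present) < 2L) stop("need at least 2 marker genes present")
  sub <- expr[present, metadata$sample_id, drop = FALSE]
  if (all(row_var(sub) == 0)) stop("markers uninformative (all constant)")
  pc <- stats::prcomp(t(sub), center = TRUE, scale. = FALSE)
  pc1 <- pc$x[, 1]
  km <- stats::kmeans(pc1, centers = matrix(range(pc1), ncol = 1))
  cl <- km$cluster
  majority <- vapply(1:2, function(k) {
    tab <- table(metadata$sex[cl == k])
    names(tab)[which.max(tab)]
  }, character(1))
  flagged <- metadata$sample_id[metadata$sex != majority[cl]]
  list(scores = pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE],
       cluster = stats::setNames(cl, metadata$sample_id), flagged = flagged)
}

#' Per-gene two-sample t-test for differential expression
#'
#' Unpaired pooled-variance t per gene between the two sexes (covariate-free
#' by design, for consistency with the downstream network comparison, which
#' is also covariate-free). The statistic is oriented female minus male.
#' Sex-chromosome genes are expected to be excluded upstream.
#'
#' @param expr Gene x sample matrix (log scale).
#' @param metadata data.frame with `sample_id` and `sex` (`"F"`/`"M"`).
#' @return data.frame: `gene`, `mean_F`, `mean_M`, `statistic` (t),
#'   `p_value`, `fdr_q` (Benjamini-Hochberg).
#' @export
differential_expression_ttest <- function(expr, metadata) {
  grp <- .split_by_sex(expr, metadata)
  if (ncol(grp$F) < 2L || ncol(grp$M) < 2L)
    stop("need at least 2 samples per sex")
  res <- row_pooled_t(grp$F, grp$M)
  if (any(res$p_value == 1 & res$t_stat == 0 &
          row_var(grp$F) == 0 & row_var(grp$M) == 0))
    warning("genes with zero variance in both groups: p recorded as 1")
  data.frame(gene = rownames(expr), mean_F = res$mean_x, mean_M = res$mean_y,
             statistic = res$t_stat, p_value = res$p_value,
             fdr_q = bh_fdr(res$p_value), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-gene two-sample F-test for differential variance
#'
#' `F = s^2_F / s^2_M` with `(n_F - 1, n_M - 1)` degrees of freedom and
#' two-sided p-value `2 * min(tail, 1 - tail)` (capped at 1). A zero
#' denominator variance yields `p = NA` with a warning.
#'
#' @inheritParams differential_expression_ttest
#' @return data.frame: `gene`, `var_F`, `var_M`, `statistic` (F), `p_value`,
#'   `fdr_q`.
#' @export
differential_variance_ftest <- function(expr, metadata) {
  grp <- .split_by_sex(expr, metadata)
  if (ncol(grp$F) < 3L || ncol(grp$M) < 3L)
    stop("need at least 3 samples per sex")
  vF <- row_var(grp$F)
  vM <- row_var(grp$M)
  f_stat <- vF / vM
  df1 <- ncol(grp$F) - 1L
  df2 <- ncol(grp$M) - 1L
  tail <- stats::pf(f_stat, df1, df2)
  p <- pmin(1, 2 * pmin(tail, 1 - tail))
  bad <- vM == 0
  if (any(bad)) {
    warning(sum(bad), " gene(s) with zero denominator variance: p = NA")
    p[bad] <- NA_real_
    f_stat[bad] <- NA_real_
  }
  data.frame(gene = rownames(expr), var_F = vF, var_M = vM,
             statistic = f_stat, p_value = p, fdr_q = bh_fdr(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

.split_by_sex <- function(expr, metadata) {
  stopifnot(all(metadata$sample_id %in% colnames(expr)),
            all(metadata$sex %in% c("F", "M")))
  list(F = expr[, metadata$sample_id[metadata$sex == "F"], drop = FALSE],
       M = expr[, metadata$sample_id[metadata$sex == "M"], drop = FALSE])
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up q-values `q_(i) = min_(j >= i) p_(j) * n / j`, capped at 1 and
#' mapped back to input order; NA p-values propagate NA q-values. Delegates
#' to [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values outside [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
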