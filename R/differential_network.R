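#' Edge-level differential statistics between two network ensembles
#'
#' For every TF->gene edge: mean score in each ensemble, their difference
#' (A minus B), an unpaired pooled-variance t-statistic across the network
#' columns, its two-sided p-value, and Benjamini-Hochberg q over all edges.
#' Edges identical and constant in both ensembles get `t = 0, p = 1`.
#'
#' @param ens_A,ens_B `network_ensemble` objects over identical TF and gene
#'   universes (e.g. female and male).
#' @return data.frame with `tf`, `gene`, `mean_A`, `mean_B`, `diff`,
#'   `t_stat`, `p_value`, `fdr_q`; one row per edge in ensemble row order.
#' @export
edge_differential <- function(ens_A, ens_B) {
  stopifnot(identical(ens_A$tfs, ens_B$tfs),
            identical(ens_A$genes, ens_B$genes))
  if (ncol(ens_A$scores) < 2L || ncol(ens_B$scores) < 2L)
    stop("ensembles must contain at least 2 networks")
  res <- row_pooled_t(ens_A$scores, ens_B$scores)
  data.frame(
    tf = rep(ens_A$tfs, times = length(ens_A$genes)),
    gene = rep(ens_A$genes, each = length(ens_A$tfs)),
    mean_A = res$mean_x, mean_B = res$mean_y, diff = res$diff,
    t_stat = res$t_stat, p_value = res$p_value, fdr_q = bh_fdr(res$p_value),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Select sex-specific edges with the three-criterion rule
#'
#' An edge is A-specific iff `diff >= diff_min`, `fdr_q < q_max`, and
#' `max(mean_A, mean_B) > mean_min` (an average edge score greater than zero
#' in at least one ensemble, an absolute difference of at least 0.25, and an
#' FDR below 1e-5, at the defaults). B-specific is symmetric with
#' `diff <= -diff_min`. The default cutoffs are calibrated so each
#' subnetwork holds roughly one to five percent of all possible edges at
#' study scale.
#'
#' @param table An [edge_differential()] table.
#' @param diff_min Minimum absolute mean-score difference.
#' @param q_max FDR significance cutoff.
#' @param mean_min Minimum of the larger ensemble mean.
#' @return List with `A_specific` and `B_specific`, each of class
#'   `sex_specific_subnetwork`: list with `label`, `edges` (data.frame
#'   subset of `table`), `target_genes`, `tf_set`.
#' @export
select_sex_specific_edges <- function(table, diff_min = 0.25, q_max = 1e-5,
                                      mean_min = 0) {
  stopifnot(is.finite(diff_min), is.finite(q_max), is.finite(mean_min))
  mean_ok <- pmax(table$mean_A, table$mean_B) > mean_min
  sel_A <- table$diff >= diff_min & table$fdr_q < q_max & mean_ok
  sel_B <- table$diff <= -diff_min & table$fdr_q < q_max & mean_ok
  mk <- function(label, sel) {
    edges <- table[sel, , drop = FALSE]
    structure(list(label = label, edges = edges,
                   target_genes = unique(edges$gene),
                   tf_set = unique(edges$tf)),
              class = "sex_specific_subnetwork")
  }
  list(A_specific = mk("A_specific", sel_A),
       B_specific = mk("B_specific", sel_B))
}

#' @export
print.sex_specific_subnetwork <- function(x, ...) {
  cat("Subnetwork", x$label, ":", nrow(x$edges), "edges,",
      length(x$target_genes), "target genes,", length(x$tf_set), "TFs\n")
  invisible(x)
}

#' Overlap of genes targeted by two sex-specific subnetworks
#'
#' Plain set algebra on the target-gene sets. A gene can be "shared" while
#' its upstream regulators differ entirely between the subnetworks; the
#' id lists let callers inspect that.
#'
#' @param subnets List with `A_specific` and `B_specific` from
#'   [select_sex_specific_edges()].
#' @return List with `A_only`, `B_only`, `shared` (gene-id vectors) and
#'   `counts` (named integer vector).
#' @export
targeted_gene_sets <- function(subnets) {
  a <- subnets$A_specific$target_genes
  b <- subnets$B_specific$target_genes
  out <- list(A_only = setdiff(a, b), B_only = setdiff(b, a),
              shared = intersect(a, b))
  out$counts <- c(A_only = length(out$A_only), B_only = length(out$B_only),
                  shared = length(out$shared))
  out
}

#' Hypergeometric (one-sided Fisher) gene-set enrichment of a gene list
#'
#' Upper-tail hypergeometric probability of the observed overlap between the
#' query genes and each annotation set (both intersected with the universe),
#' equivalent to a one-sided Fisher exact test, with BH correction across
#' sets.
#'
#' @param query_genes Genes of interest (must lie in `universe`).
#' @param universe Background gene universe.
#' @param gene_sets Named list of gene-id vectors (GMT-style).
#' @return data.frame: `set`, `set_size` (in-universe), `overlap`,
#'   `p_value`, `fdr_q`.
#' @export
fisher_enrichment <- function(query_genes, universe, gene_sets) {
  if (length(universe) == 0) stop("empty universe")
  if (!all(query_genes %in% universe))
    stop("query genes outside the universe")
  query_genes <- unique(query_genes)
  N <- length(unique(universe))
  n <- length(query_genes)
  res <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    k <- length(intersect(set, query_genes))
    p <- stats::phyper(k - 1, length(set), N - length(set), n,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set), overlap = k, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr_q <- bh_fdr(out$p_value)
  rownames(out) <- NULL
  out
}

#' Per-network degree table of an ensemble
#'
#' `gene_in`: each gene's in-degree (sum of the weights of all edges
#' pointing to it) in each network. `tf_out`: each TF's out-degree (sum of
#' the weights of all outgoing edges). For every network, total in-degree
#' equals total out-degree (both are the total edge weight).
#'
#' @param ens A `network_ensemble`.
#' @param axis `"gene_in"` or `"tf_out"`.
#' @return Entity x network numeric matrix with attribute `axis`; row names
#'   are genes or TFs, columns the ensemble's networks.
#' @export
degree_table <- function(ens, axis = c("gene_in", "tf_out")) {
  axis <- match.arg(axis)
  nT <- length(ens$tfs)
  nG <- length(ens$genes)
  nN <- ncol(ens$scores)
  if (nN == 0) stop("empty ensemble")
  arr <- array(ens$scores, dim = c(nT, nG, nN))
  if (axis == "gene_in") {
    vals <- apply(arr, 3L, colSums)  # gene x network
    rownames(vals) <- ens$genes
  } else {
    vals <- apply(arr, 3L, rowSums)  # tf x network
    rownames(vals) <- ens$tfs
  }
  colnames(vals) <- colnames(ens$scores)
  attr(vals, "axis") <- axis
  vals
}

#' Gene-by-network table of one TF's edge weights
#'
#' @param ens A `network_ensemble`.
#' @param tf TF id present in the ensemble.
#' @return Gene x network matrix of that TF's edge scores.
#' @export
tf_specific_table <- function(ens, tf) {
  ti <- match(tf, ens$tfs)
  if (is.na(ti)) stop("unknown TF: ", tf)
  nT <- length(ens$tfs)
  idx <- ti + (seq_along(ens$genes) - 1L) * nT
  out <- ens$scores[idx, , drop = FALSE]
  rownames(out) <- ens$genes
  out
}

#' Hierarchical clustering of the edge t-statistic matrix
#'
#' Reshapes the per-edge t-statistics into a gene x TF matrix and clusters
#' rows and columns separately with complete linkage on the
#' `1 - Pearson correlation` distance. Constant rows (or columns) have
#' undefined correlation; their correlation is set to 0 (distance 1) with a
#' warning.
#'
#' @param table An [edge_differential()] table (complete edge grid).
#' @return List with `matrix` (gene x TF t-statistics), `row_order` and
#'   `col_order` (leaf orders as ids), `row_hclust`, `col_hclust`.
#' @export
edge_tstat_clustering <- function(table) {
  tfs <- unique(table$tf)
  genes <- unique(table$gene)
  if (nrow(table) != length(tfs) * length(genes))
    stop("edge table is not a complete TF x gene grid")
  m <- t(matrix(table$t_stat, nrow = length(tfs), ncol = length(genes),
                dimnames = list(tfs, genes)))
  hr <- stats::hclust(.cor_dist(m), method = "complete")
  hc <- stats::hclust(.cor_dist(t(m)), method = "complete")
  list(matrix = m, row_order = rownames(m)[hr$order],
       col_order = colnames(m)[hc$order], row_hclust = hr, col_hclust = hc)
}

# 1 - Pearson distance between rows; undefined correlations (constant rows)
# set to 0 with a warning.
.cor_dist <- function(m) {
  cc <- suppressWarnings(stats::cor(t(m)))
  if (anyNA(cc)) {
    warning("constant rows: correlation set to 0 (distance 1)")
    cc[is.na(cc)] <- 0
  }
  diag(cc) <- 1
  stats::as.dist(1 - cc)
}
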