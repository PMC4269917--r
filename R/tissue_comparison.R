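#' Per-TF differential-targeting profiles per tissue
#'
#' For each TF and each tissue, builds the TF-specific gene-by-network table
#' across the two sex ensembles (female columns first) and runs [gsea()] on
#' the selected gene sets, collecting the signed `-log10(FDR)` score. The
#' result is one TF x gene-set signed-score matrix per tissue, with an
#' identical set order, ready for the cross-tissue discordance screen.
#'
#' @param ensembles Named list, one element per tissue, each a list with
#'   elements `female` and `male` (`network_ensemble` objects over identical
#'   TF/gene universes).
#' @param gene_sets Named list of gene-id vectors.
#' @param selected_sets Character vector of set names to profile (a subset
#'   of `names(gene_sets)`), e.g. from [top_differential_sets()].
#' @param n_perm,weight_p,min_size,max_size Passed to [gsea()].
#' @param seed Integer seed; each TF/tissue GSEA gets a derived child seed.
#' @return Named list (per tissue) of TF x set numeric matrices of signed
#'   scores; class `tf_function_profiles`.
#' @export
tf_function_profiles <- function(ensembles, gene_sets, selected_sets,
                                 n_perm = 200L, seed = 1L, weight_p = 1,
                                 min_size = 3L, max_size = 500L) {
  if (!all(selected_sets %in% names(gene_sets)))
    stop("selected_sets must name entries of gene_sets")
  sets <- gene_sets[selected_sets]
  out <- list()
  for (ti in names(ensembles)) {
    ensF <- ensembles[[ti]]$female
    ensM <- ensembles[[ti]]$male
    stopifnot(identical(ensF$tfs, ensM$tfs),
              identical(ensF$genes, ensM$genes))
    labs <- c(rep("F", ncol(ensF$scores)), rep("M", ncol(ensM$scores)))
    prof <- matrix(NA_real_, length(ensF$tfs), length(selected_sets),
                   dimnames = list(ensF$tfs, selected_sets))
    for (k in seq_along(ensF$tfs)) {
      tf <- ensF$tfs[k]
      tab <- cbind(tf_specific_table(ensF, tf), tf_specific_table(ensM, tf))
      res <- gsea(tab, labs, sets, n_perm = n_perm,
                  seed = child_seed(seed, k + 131 * match(ti, names(ensembles))),
                  weight_p = weight_p, min_size = min_size,
                  max_size = max_size, positive_class = "F")
      prof[k, res$set] <- res$signed_score
    }
    out[[ti]] <- prof
  }
  structure(out, class = "tf_function_profiles")
}

#' Pick the most differentially-targeted gene sets in each direction
#'
#' Returns the `n_each` sets with the most positive signed scores (enriched
#' toward the positive class) plus the `n_each` most negative, ordered by
#' signed score with deterministic name tie-breaks.
#'
#' @param results An [gsea()] result.
#' @param n_each Sets to take per direction (default 5, i.e. ten sets).
#' @return Character vector of set names.
#' @export
top_differential_sets <- function(results, n_each = 5L) {
  ord <- order(-results$signed_score, results$set)
  top_pos <- results$set[ord][seq_len(min(n_each, nrow(results)))]
  ord_neg <- order(results$signed_score, results$set)
  top_neg <- results$set[ord_neg][seq_len(min(n_each, nrow(results)))]
  unique(c(top_pos, rev(top_neg)))
}

#' Cross-tissue Spearman discordance screen
#'
#' For each TF, the Spearman rank correlation between its signed-score
#' profile (over the selected sets) in the two tissues. TFs with strongly
#' negative correlation target these functions in *opposite* sex directions
#' in the two tissues -- the candidate disease-specific regulators. Constant
#' profiles have undefined rank correlation and are reported `NA` and
#' excluded from the discordant list with a warning. Ties get average ranks.
#'
#' @param profile_a,profile_b TF x set signed-score matrices with identical
#'   dimnames (e.g. sputum and blood from [tf_function_profiles()]).
#' @param rho_cutoff Discordance threshold (default -0.4).
#' @return List with `rho` (named numeric vector per TF) and `discordant`
#'   (TF ids with `rho < rho_cutoff`).
#' @export
tissue_discordance <- function(profile_a, profile_b, rho_cutoff = -0.4) {
  stopifnot(identical(dimnames(profile_a), dimnames(profile_b)))
  if (ncol(profile_a) < 3L)
    stop("need >= 3 selected sets for a non-degenerate Spearman correlation")
  rho <- vapply(seq_len(nrow(profile_a)), function(i)
    suppressWarnings(stats::cor(profile_a[i, ], profile_b[i, ],
                                method = "spearman")), numeric(1))
  names(rho) <- rownames(profile_a)
  if (anyNA(rho))
    warning("constant profile(s): Spearman undefined for ",
            paste(names(rho)[is.na(rho)], collapse = ", "),
            "; excluded from selection")
  list(rho = rho, discordant = names(rho)[!is.na(rho) & rho < rho_cutoff])
}

#' Extract the core sex-specific subnetwork for one tissue
#'
#' Filters the tissue's sex-specific edge lists to edges from a discordant
#' TF to a gene annotated to one of the selected sets, retaining each edge's
#' sex label. The result is the "core" regulatory subnetwork connecting
#' candidate disease-specific drivers to the top differentially-targeted
#' functions.
#'
#' @param subnets List with `A_specific` and `B_specific`
#'   ([select_sex_specific_edges()] output for one tissue).
#' @param discordant_tfs TF ids (e.g. from [tissue_discordance()]).
#' @param selected_sets Names of gene sets whose annotated genes to keep.
#' @param gene_sets Named list of gene-id vectors.
#' @param tissue Optional tissue label recorded on every edge.
#' @return data.frame with `tf`, `gene`, `label` (the source subnetwork's
#'   label), `tissue`.
#' @export
extract_core_subnetwork <- function(subnets, discordant_tfs, selected_sets,
                                    gene_sets, tissue = NA_character_) {
  set_genes <- unique(unlist(gene_sets[selected_sets], use.names = FALSE))
  pick <- function(sn) {
    e <- sn$edges
    keep <- e$tf %in% discordant_tfs & e$gene %in% set_genes
    if (!any(keep))
      return(data.frame(tf = character(0), gene = character(0),
                        label = character(0), tissue = character(0)))
    data.frame(tf = e$tf[keep], gene = e$gene[keep], label = sn$label,
               tissue = tissue, stringsAsFactors = FALSE)
  }
  out <- rbind(pick(subnets$A_specific), pick(subnets$B_specific))
  rownames(out) <- NULL
  out
}
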