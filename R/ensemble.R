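#' Jack-knife sampling plan for one sex/tissue group
#'
#' Draws `reps` replicates, each a uniform sample of `k` distinct subjects of
#' the group, independently across replicates (a subject may recur across
#' replicates; "without replacement" applies within a replicate). With
#' exactly `k` subjects in the group every replicate is the full group.
#'
#' @param metadata Cohort metadata (one row per sample) with `subject_id`,
#'   `sex`, `tissue` columns.
#' @param sex `"F"` or `"M"`.
#' @param tissue Tissue name.
#' @param k Subjects per replicate (default 10).
#' @param reps Number of replicates (default 100).
#' @param seed Integer seed.
#' @return Object of class `jackknife_plan`: list with `group` (named
#'   character vector sex/tissue), `replicates` (list of subject-id vectors),
#'   `k`, `reps`, `mode`, `seed`.
#' @export
jackknife_plan <- function(metadata, sex, tissue, k = 10L, reps = 100L,
                           seed = 1L) {
  subjects <- unique(metadata$subject_id[metadata$sex == sex &
                                           metadata$tissue == tissue])
  if (length(subjects) < k)
    stop("group ", sex, "/", tissue, " has ", length(subjects),
         " subjects; need >= ", k)
  replicates <- with_seed(seed, lapply(seq_len(reps), function(i)
    sample(subjects, k)))
  structure(list(group = c(sex = sex, tissue = tissue),
                 replicates = replicates, k = as.integer(k),
                 reps = as.integer(reps), mode = "random",
                 seed = as.integer(seed)),
            class = "jackknife_plan")
}

#' Covariate-matched female/male jack-knife plan pair
#'
#' Female replicates are drawn at random; each male replicate is then chosen
#' to match its female partner's GOLD-stage composition exactly and, within
#' stage, to minimize the summed standardized (age, pack-years) Euclidean
#' distance by greedy nearest-neighbour assignment. Deterministic given the
#' seed.
#'
#' @inheritParams jackknife_plan
#' @return List with elements `female` and `male`, both `jackknife_plan`
#'   objects with `mode = "covariate_matched"`.
#' @export
matched_jackknife_plans <- function(metadata, tissue, k = 10L, reps = 100L,
                                    seed = 1L) {
  md <- metadata[metadata$tissue == tissue & !duplicated(metadata$subject_id), ]
  fem <- md[md$sex == "F", ]
  mal <- md[md$sex == "M", ]
  if (nrow(fem) < k || nrow(mal) < k)
    stop("fewer than ", k, " subjects in a sex group for tissue ", tissue)
  sd_age <- stats::sd(md$age)
  sd_py <- stats::sd(md$pack_years)
  f_plan <- jackknife_plan(metadata, "F", tissue, k = k, reps = reps,
                           seed = seed)
  m_reps <- lapply(f_plan$replicates, function(frep) {
    used <- character(0)
    for (sid in frep) {
      frow <- fem[fem$subject_id == sid, ]
      cand <- mal[mal$gold_stage == frow$gold_stage &
                    !(mal$subject_id %in% used), ]
      if (nrow(cand) == 0)
        stop("no unused male subject with GOLD stage ", frow$gold_stage,
             " available for matching")
      d <- ((cand$age - frow$age) / sd_age)^2 +
        ((cand$pack_years - frow$pack_years) / sd_py)^2
      used <- c(used, cand$subject_id[which.min(d)])
    }
    used
  })
  m_plan <- structure(list(group = c(sex = "M", tissue = tissue),
                           replicates = m_reps, k = as.integer(k),
                           reps = as.integer(reps),
                           mode = "covariate_matched", seed = as.integer(seed)),
                      class = "jackknife_plan")
  f_plan$mode <- "covariate_matched"
  list(female = f_plan, male = m_plan)
}

#' @export
print.jackknife_plan <- function(x, ...) {
  cat("Jack-knife plan:", x$group[["sex"]], "/", x$group[["tissue"]], "-",
      x$reps, "replicates of", x$k, "subjects (", x$mode, ")\n")
  invisible(x)
}

#' Build a network ensemble from a jack-knife plan
#'
#' For each replicate, computes co-expression on that replicate's samples and
#' runs [panda()] with the shared motif prior and PPI, stacking the final
#' edge scores as one column of an edge x network matrix. Edge rows follow
#' column-major order of the TF x gene score matrix (TF index varying
#' fastest), with row names `tf::gene`.
#'
#' @param expr Gene x sample matrix covering at least the prior's genes and
#'   all plan samples.
#' @param metadata Cohort metadata with `sample_id`, `subject_id`, `tissue`.
#' @param plan A [jackknife_plan()].
#' @param prior TF x gene motif prior matrix (dimnames required).
#' @param ppi TF x TF interaction matrix.
#' @param alpha,tol,max_iter Passed to [panda()].
#' @return Object of class `network_ensemble`: list with `tfs`, `genes`,
#'   `scores` (edge x network matrix), `plan`, `panda_config`.
#' @export
build_ensemble <- function(expr, metadata, plan, prior, ppi,
                           alpha = 0.1, tol = 1e-3, max_iter = 200L) {
  stopifnot(inherits(plan, "jackknife_plan"))
  tfs <- rownames(prior)
  genes <- colnames(prior)
  if (!all(genes %in% rownames(expr)))
    stop("expression matrix is missing prior genes")
  expr <- expr[genes, , drop = FALSE]
  tissue <- plan$group[["tissue"]]
  cols <- matrix(NA_real_, nrow = length(tfs) * length(genes),
                 ncol = plan$reps)
  for (i in seq_len(plan$reps)) {
    sids <- metadata$sample_id[metadata$tissue == tissue &
                                 metadata$subject_id %in% plan$replicates[[i]]]
    if (length(sids) != plan$k)
      stop("replicate ", i, ": found ", length(sids), " samples, expected ",
           plan$k)
    net <- tryCatch(
      panda(prior, ppi, coexpression(expr[, sids, drop = FALSE]),
            alpha = alpha, tol = tol, max_iter = max_iter),
      error = function(e) stop("replicate ", i, " failed: ",
                               conditionMessage(e), call. = FALSE))
    cols[, i] <- as.vector(net$edge_scores)
  }
  rownames(cols) <- paste(rep(tfs, times = length(genes)),
                          rep(genes, each = length(tfs)), sep = "::")
  colnames(cols) <- sprintf("net%03d", seq_len(plan$reps))
  structure(list(tfs = tfs, genes = genes, scores = cols, plan = plan,
                 panda_config = list(alpha = alpha, tol = tol,
                                     max_iter = max_iter)),
            class = "network_ensemble")
}

#' @export
print.network_ensemble <- function(x, ...) {
  cat("Network ensemble:", length(x$tfs), "TFs x", length(x$genes),
      "genes,", ncol(x$scores), "networks (",
      x$plan$group[["sex"]], "/", x$plan$group[["tissue"]], ")\n")
  invisible(x)
}

#' Permutation controls for the network pipeline
#'
#' `gene_labels` permutes the gene row labels of the expression matrix once
#' (priors untouched), destroying the gene-to-prior correspondence while
#' keeping the expression correlation structure; the permutation is redrawn
#' until it differs from the identity whenever more than 3 genes are
#' permuted. `sex_labels` permutes subjects' sex labels once at the subject
#' level, exactly preserving the female/male group sizes.
#'
#' @param expr Gene x sample matrix (used by `gene_labels`).
#' @param metadata Cohort metadata (used by `sex_labels`).
#' @param mode `"gene_labels"` or `"sex_labels"`.
#' @param seed Integer seed.
#' @return List with `expr` and `metadata`; only the element touched by
#'   `mode` is modified.
#' @export
permutation_control <- function(expr, metadata,
                                mode = c("gene_labels", "sex_labels"),
                                seed = 1L) {
  mode <- match.arg(mode)
  with_seed(seed, {
    if (mode == "gene_labels") {
      n <- nrow(expr)
      perm <- sample.int(n)
      while (n > 3L && all(perm == seq_len(n))) perm <- sample.int(n)
      rownames(expr) <- rownames(expr)[perm]
    } else {
      subj <- unique(metadata[, c("subject_id", "sex")])
      new_sex <- sample(subj$sex)
      metadata$sex <- new_sex[match(metadata$subject_id, subj$subject_id)]
    }
    list(expr = expr, metadata = metadata)
  })
}
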