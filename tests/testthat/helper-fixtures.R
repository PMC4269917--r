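# Shared fixture builders. Heavy pipeline objects are memoised so different
# test files can reuse the same runs.

`%||%` <- function(a, b) if (is.null(a)) b else a

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# Wrap bare score matrices as a network_ensemble for edge-level unit tests.
fake_ensemble <- function(scores, tfs, genes) {
  stopifnot(nrow(scores) == length(tfs) * length(genes))
  rownames(scores) <- paste(rep(tfs, times = length(genes)),
                            rep(genes, each = length(tfs)), sep = "::")
  structure(list(tfs = tfs, genes = genes, scores = scores,
                 plan = NULL, panda_config = NULL),
            class = "network_ensemble")
}

# Small planted system: one female-sputum co-regulation module.
make_planted_system <- function(seed, n_genes = 120L, n_tf = 10L,
                                n_f = 15L, n_m = 20L,
                                module_tfs = 2L, module_genes = 20L,
                                coupling = 1.0, tissues = c("sputum", "blood")) {
  tfs <- sprintf("TF%03d", seq_len(module_tfs))
  genes <- sprintf("G%04d", seq_len(module_genes))
  mods <- list(module_spec("F", "sputum", tfs, genes, coupling))
  truth <- generate_regulatory_truth(truth_config(
    n_tf = n_tf, n_genes = n_genes, prior_density = 0.08, ppi_density = 0.15,
    modules = mods, decoys_per_module = 3L, seed = child_seed(seed, 11)))
  cohort <- generate_cohort(cohort_config(
    n_female = n_f, n_male = n_m, tissues = tissues, n_genes = n_genes,
    modules = mods, seed = child_seed(seed, 12)))
  list(truth = truth, cohort = cohort, module = mods[[1]])
}

# Female and male ensembles for one tissue of a planted system.
build_sex_ensembles <- function(sys, tissue, reps, k = 10L, seed = 1L,
                                expr = NULL, metadata = NULL) {
  expr <- expr %||% sys$cohort$expression[[tissue]]
  metadata <- metadata %||% sys$cohort$metadata
  pf <- jackknife_plan(metadata, "F", tissue, k = k, reps = reps,
                       seed = child_seed(seed, 21))
  pm <- jackknife_plan(metadata, "M", tissue, k = k, reps = reps,
                       seed = child_seed(seed, 22))
  list(female = build_ensemble(expr, metadata, pf, sys$truth$motif_prior,
                               sys$truth$ppi),
       male = build_ensemble(expr, metadata, pm, sys$truth$motif_prior,
                             sys$truth$ppi))
}

# Differential-targeting run at the scale used by the recovery and control
# experiments: one female-sputum module (3 TFs x 30 genes, coupling 1.0),
# female and male sputum ensembles of 20 jack-knife networks each, edge
# selection, and in-degree GSEA over the planted set plus size-matched
# decoys. `control` optionally permutes gene labels or sex labels first.
dt_run <- function(seed, control = c("none", "gene_labels", "sex_labels"),
                   n_genes = 300L, n_tf = 20L, reps = 20L) {
  control <- match.arg(control)
  cached(paste("dt", seed, control, n_genes, n_tf, reps, sep = "_"), {
    mod <- module_spec("F", "sputum", sprintf("TF%03d", 1:3),
                       sprintf("G%04d", 1:30), coupling = 1.0)
    truth <- generate_regulatory_truth(truth_config(
      n_tf = n_tf, n_genes = n_genes, prior_density = 0.05,
      ppi_density = 0.1, modules = list(mod), decoys_per_module = 5L,
      extra_set_sizes = rep(30L, 8L), seed = child_seed(seed, 1)))
    # the 42/84 split is the design the sex-label permutation is defined on;
    # smaller groups leave too much residual signal in a single permutation
    cohort <- generate_cohort(cohort_config(
      n_female = 42L, n_male = 84L, tissues = "sputum", n_genes = n_genes,
      modules = list(mod), seed = child_seed(seed, 2)))
    expr <- cohort$expression$sputum
    metadata <- cohort$metadata
    if (control != "none") {
      perm <- permutation_control(expr, metadata, mode = control,
                                  seed = child_seed(seed, 3))
      expr <- perm$expr
      metadata <- perm$metadata
    }
    ens <- build_sex_ensembles(list(truth = truth), "sputum", reps = reps,
                               seed = seed, expr = expr, metadata = metadata)
    ed <- edge_differential(ens$female, ens$male)
    subnets <- select_sex_specific_edges(ed)
    tab <- cbind(degree_table(ens$female, "gene_in"),
                 degree_table(ens$male, "gene_in"))
    labs <- rep(c("F", "M"), each = reps)
    res <- gsea(tab, labs, truth$gene_sets, n_perm = 500L,
                seed = child_seed(seed, 4), min_size = 15L,
                positive_class = "F")
    list(gsea = res, planted_set = "MODULE_F_sputum_1",
         edge_table = ed, subnets = subnets,
         n_selected = nrow(subnets$A_specific$edges) +
           nrow(subnets$B_specific$edges),
         ensembles = ens, truth = truth)
  })
}

# Cross-tissue discordance run: TF001 drives two gene sets toward females in
# sputum and toward males in blood, and two other sets the opposite way, so
# its sputum/blood signed-score profiles anticorrelate by construction.
disc_run <- function(seed, n_genes = 160L, n_tf = 10L, reps = 12L) {
  cached(paste("disc", seed, sep = "_"), {
    gs <- function(i) sprintf("G%04d", ((i - 1) * 20 + 1):(i * 20))
    tf <- "TF001"
    mods <- list(
      module_spec("F", "sputum", tf, gs(1), 1.2),
      module_spec("F", "sputum", tf, gs(2), 1.2),
      module_spec("M", "blood", tf, gs(1), 1.2),
      module_spec("M", "blood", tf, gs(2), 1.2),
      module_spec("M", "sputum", tf, gs(3), 1.2),
      module_spec("M", "sputum", tf, gs(4), 1.2),
      module_spec("F", "blood", tf, gs(3), 1.2),
      module_spec("F", "blood", tf, gs(4), 1.2)
    )
    truth <- generate_regulatory_truth(truth_config(
      n_tf = n_tf, n_genes = n_genes, prior_density = 0.08,
      ppi_density = 0.15, modules = mods, decoys_per_module = 0L,
      extra_set_sizes = c(20L, 20L), seed = child_seed(seed, 31)))
    cohort <- generate_cohort(cohort_config(
      n_female = 15L, n_male = 15L, tissues = c("sputum", "blood"),
      n_genes = n_genes, modules = mods, seed = child_seed(seed, 32)))
    sys <- list(truth = truth, cohort = cohort)
    ens <- list(sputum = build_sex_ensembles(sys, "sputum", reps = reps,
                                             seed = child_seed(seed, 33)),
                blood = build_sex_ensembles(sys, "blood", reps = reps,
                                            seed = child_seed(seed, 34)))
    selected <- c("MODULE_F_sputum_1", "MODULE_F_sputum_2",
                  "MODULE_M_sputum_5", "MODULE_M_sputum_6",
                  "DECOY_X1", "DECOY_X2")
    prof <- tf_function_profiles(ens, truth$gene_sets, selected,
                                 n_perm = 200L, seed = child_seed(seed, 35),
                                 min_size = 10L)
    disc <- tissue_discordance(prof$sputum, prof$blood)
    list(truth = truth, ensembles = ens, profiles = prof,
         discordance = disc, selected = selected)
  })
}
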