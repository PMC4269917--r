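#' Module specification for planted sex- and tissue-restricted co-regulation
#'
#' Describes one planted co-regulation module: in the designated sex/tissue
#' stratum, each module TF gets an i.i.d. standard-normal latent activity per
#' sample and every module gene receives `coupling` times the sum of its TFs'
#' activities on top of its baseline. Outside the stratum the module is
#' silent, so module genes are differentially *co-expressed* without being
#' differentially expressed on average -- the regime the network comparison
#' is designed to detect.
#'
#' @param sex `"F"` or `"M"`.
#' @param tissue Tissue name (must be one of the cohort's tissues).
#' @param tf_ids Character vector of TF ids driving the module.
#' @param gene_ids Character vector of target gene ids.
#' @param coupling Positive real coupling strength (per-TF activity weight).
#' @return A `module_spec` list.
#' @export
module_spec <- function(sex, tissue, tf_ids, gene_ids, coupling = 1.0) {
  stopifnot(sex %in% c("F", "M"), is.character(tf_ids), is.character(gene_ids),
            length(tf_ids) >= 1, length(gene_ids) >= 1, coupling >= 0)
  structure(list(sex = sex, tissue = tissue, tf_ids = tf_ids,
                 gene_ids = gene_ids, coupling = coupling),
            class = "module_spec")
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study design the pipeline targets: 42 female and 84
#' male COPD subjects with both sputum and blood expression, 24 bimodal
#' marker genes standing in for Y-chromosome probe sets, log-intensity scale
#' expression with unit Gaussian noise, females younger and with fewer
#' pack-years on average, and a GOLD-stage distribution shared between sexes.
#'
#' @param n_female,n_male Subjects per sex (each must be >= 10: the
#'   jack-knife draws 10 subjects per replicate).
#' @param tissues Character vector of tissue names.
#' @param n_genes Autosomal gene count.
#' @param n_marker Number of sex-marker genes (bimodal, high in males).
#' @param noise_sd Gaussian noise sd on the log-intensity scale.
#' @param baseline_mean,baseline_sd Distribution of per-gene baselines.
#' @param marker_high,marker_low Marker means in males / females.
#' @param modules List of [module_spec()] objects to plant.
#' @param de_genes Named numeric vector: gene id -> mean shift added to
#'   female samples (both tissues).
#' @param dv_genes Named numeric vector: gene id -> variance inflation factor
#'   applied to female samples' noise (both tissues).
#' @param n_mislabeled Number of subjects whose marker expression follows the
#'   opposite sex (planted QC failures).
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_female = 42L, n_male = 84L,
                          tissues = c("sputum", "blood"),
                          n_genes = 2000L, n_marker = 24L,
                          noise_sd = 1, baseline_mean = 7, baseline_sd = 1,
                          marker_high = 9, marker_low = 3,
                          modules = list(), de_genes = NULL, dv_genes = NULL,
                          n_mislabeled = 0L, seed = 1L) {
  if (n_female < 10L || n_male < 10L)
    stop("each sex needs at least 10 subjects (jack-knife replicate size)")
  if (anyDuplicated(tissues)) stop("duplicate tissue names")
  for (m in modules) {
    if (!inherits(m, "module_spec")) stop("modules must be module_spec objects")
    if (!m$tissue %in% tissues)
      stop("module references unknown tissue: ", m$tissue)
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic two-tissue, two-sex expression cohort
#'
#' Draws subject covariates, marker-gene expression separating the sexes, and
#' per-tissue gene x sample expression matrices composed of per-gene
#' baselines, planted module contributions (latent TF activities), planted
#' mean shifts (`de_genes`), variance inflation (`dv_genes`), and Gaussian
#' noise. Autosomal gene ids are `G0001...`; marker ids `MKR01...` are kept
#' out of the autosomal universe, mirroring the exclusion of sex-chromosome
#' genes from the network analysis.
#'
#' @param config A [cohort_config()].
#' @return Object of class `synthetic_cohort`: list with `expression` (named
#'   list of gene x sample matrices, one per tissue; rows = autosomal genes
#'   then markers), `metadata` (one row per sample: `sample_id`,
#'   `subject_id`, `tissue`, `sex`, `age`, `pack_years`, `gold_stage`),
#'   `gene_ids` (autosomal universe), `marker_genes`, `mislabeled` (subject
#'   ids), `modules`, `seed`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cf <- config
  with_seed(cf$seed, {
    n_sub <- cf$n_female + cf$n_male
    subject_id <- sprintf("SUBJ%03d", seq_len(n_sub))
    sex <- rep(c("F", "M"), c(cf$n_female, cf$n_male))
    age <- round(stats::rnorm(n_sub, ifelse(sex == "F", 60, 64), 7), 1)
    pack_years <- round(pmax(5, stats::rnorm(n_sub,
                                             ifelse(sex == "F", 35, 47), 12)), 1)
    gold_stage <- sample(c(2L, 3L, 4L), n_sub, replace = TRUE,
                         prob = c(0.5, 0.35, 0.15))
    mislabeled <- character(0)
    if (cf$n_mislabeled > 0)
      mislabeled <- sort(sample(subject_id, cf$n_mislabeled))

    gene_ids <- sprintf("G%04d", seq_len(cf$n_genes))
    marker_genes <- sprintf("MKR%02d", seq_len(cf$n_marker))
    for (nm in names(cf$de_genes))
      if (!nm %in% gene_ids) stop("de_gene not in gene universe: ", nm)
    for (nm in names(cf$dv_genes))
      if (!nm %in% gene_ids) stop("dv_gene not in gene universe: ", nm)
    for (m in cf$modules)
      if (!all(m$gene_ids %in% gene_ids))
        stop("module gene ids outside the gene universe")

    baseline <- stats::rnorm(cf$n_genes, cf$baseline_mean, cf$baseline_sd)
    names(baseline) <- gene_ids

    # sex of the marker-expression generator: flipped for mislabeled subjects
    marker_sex <- ifelse(subject_id %in% mislabeled,
                         ifelse(sex == "F", "M", "F"), sex)

    meta <- list()
    expression <- list()
    for (ti in cf$tissues) {
      sample_id <- paste(subject_id, ti, sep = "_")
      meta[[ti]] <- data.frame(sample_id = sample_id, subject_id = subject_id,
                               tissue = ti, sex = sex, age = age,
                               pack_years = pack_years,
                               gold_stage = gold_stage,
                               stringsAsFactors = FALSE)
      noise_sd_mat <- matrix(cf$noise_sd, cf$n_genes, n_sub)
      for (nm in names(cf$dv_genes))
        noise_sd_mat[match(nm, gene_ids), sex == "F"] <-
          cf$noise_sd * sqrt(cf$dv_genes[[nm]])
      X <- baseline +
        matrix(stats::rnorm(cf$n_genes * n_sub), cf$n_genes, n_sub) * noise_sd_mat
      for (nm in names(cf$de_genes))
        X[match(nm, gene_ids), sex == "F"] <-
          X[match(nm, gene_ids), sex == "F"] + cf$de_genes[[nm]]
      for (m in cf$modules) {
        if (m$tissue != ti) next
        in_stratum <- sex == m$sex
        act <- matrix(stats::rnorm(length(m$tf_ids) * sum(in_stratum)),
                      nrow = length(m$tf_ids))
        contrib <- m$coupling * colSums(act)
        gi <- match(m$gene_ids, gene_ids)
        X[gi, in_stratum] <- X[gi, in_stratum] +
          matrix(contrib, length(gi), sum(in_stratum), byrow = TRUE)
      }
      mk_mean <- ifelse(marker_sex == "M", cf$marker_high, cf$marker_low)
      MK <- matrix(rep(mk_mean, each = cf$n_marker), cf$n_marker, n_sub) +
        matrix(stats::rnorm(cf$n_marker * n_sub, 0, 0.5), cf$n_marker, n_sub)
      X <- rbind(X, MK)
      dimnames(X) <- list(c(gene_ids, marker_genes), sample_id)
      expression[[ti]] <- X
    }
    metadata <- do.call(rbind, meta)
    rownames(metadata) <- NULL

    structure(
      list(expression = expression, metadata = metadata, gene_ids = gene_ids,
           marker_genes = marker_genes, mislabeled = mislabeled,
           modules = cf$modules, config = cf, seed = cf$seed),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", sum(x$metadata$sex == "F" & !duplicated(x$metadata$subject_id)),
      "F /", sum(x$metadata$sex == "M" & !duplicated(x$metadata$subject_id)),
      "M subjects;", length(x$gene_ids), "autosomal genes +",
      length(x$marker_genes), "markers; tissues:",
      paste(names(x$expression), collapse = ", "), "\n")
  invisible(x)
}

#' Configuration for the synthetic regulatory ground truth
#'
#' @param n_tf Number of TFs (default 130, the size of a core vertebrate
#'   motif collection).
#' @param n_genes Gene universe size (ids `G0001...`, matching
#'   [generate_cohort()]).
#' @param prior_density Probability that a background TF->gene prior edge is
#'   present, in \[0, 1\].
#' @param ppi_density Probability of a background TF-TF interaction.
#' @param modules List of [module_spec()]; their TF->gene pairs are forced
#'   into the prior and each module's gene set is emitted as a gene set.
#' @param decoys_per_module Decoy gene sets per planted module, size-matched
#'   and sampled without replacement from the universe.
#' @param extra_set_sizes Sizes of additional decoy sets when no modules are
#'   planted (or extra padding sets).
#' @param seed Integer seed.
#' @return A `truth_config` list.
#' @export
truth_config <- function(n_tf = 130L, n_genes = 2000L, prior_density = 0.05,
                         ppi_density = 0.1, modules = list(),
                         decoys_per_module = 5L, extra_set_sizes = integer(0),
                         seed = 1L) {
  if (prior_density < 0 || prior_density > 1) stop("prior_density outside [0, 1]")
  if (ppi_density < 0 || ppi_density > 1) stop("ppi_density outside [0, 1]")
  for (m in modules) {
    if (!inherits(m, "module_spec")) stop("modules must be module_spec objects")
    if (length(m$gene_ids) > n_genes || length(m$tf_ids) > n_tf)
      stop("module larger than the universe")
  }
  structure(as.list(environment()), class = "truth_config")
}

#' Generate synthetic regulatory ground truth
#'
#' Builds the motif prior (background Bernoulli edges plus every planted
#' module TF->gene pair), a symmetric TF-TF interaction matrix with unit
#' diagonal, and a gene-set collection holding each planted module's gene set
#' plus size-matched decoys.
#'
#' @param config A [truth_config()].
#' @return Object of class `regulatory_truth`: list with `tfs`, `genes`,
#'   `motif_prior` (TF x gene 0/1), `ppi` (TF x TF 0/1, diag 1),
#'   `planted_modules`, `gene_sets` (named list of gene-id vectors; planted
#'   sets are named `MODULE_<sex>_<tissue>_<i>`), `seed`.
#' @export
generate_regulatory_truth <- function(config) {
  stopifnot(inherits(config, "truth_config"))
  cf <- config
  with_seed(cf$seed, {
    tfs <- sprintf("TF%03d", seq_len(cf$n_tf))
    genes <- sprintf("G%04d", seq_len(cf$n_genes))
    prior <- matrix(stats::rbinom(cf$n_tf * cf$n_genes, 1, cf$prior_density),
                    cf$n_tf, cf$n_genes, dimnames = list(tfs, genes))
    ppi <- matrix(0L, cf$n_tf, cf$n_tf, dimnames = list(tfs, tfs))
    up <- upper.tri(ppi)
    ppi[up] <- stats::rbinom(sum(up), 1, cf$ppi_density)
    ppi <- ppi + t(ppi)
    diag(ppi) <- 1L

    modules <- lapply(cf$modules, function(m) {
      if (!all(m$tf_ids %in% tfs)) stop("module TF ids outside the TF universe")
      if (!all(m$gene_ids %in% genes)) stop("module gene ids outside the gene universe")
      prior[m$tf_ids, m$gene_ids] <<- 1L
      m
    })

    gene_sets <- list()
    for (i in seq_along(modules)) {
      m <- modules[[i]]
      gene_sets[[sprintf("MODULE_%s_%s_%d", m$sex, m$tissue, i)]] <- m$gene_ids
      for (j in seq_len(cf$decoys_per_module)) {
        gene_sets[[sprintf("DECOY_M%d_%d", i, j)]] <-
          sort(sample(genes, length(m$gene_ids)))
      }
    }
    for (j in seq_along(cf$extra_set_sizes)) {
      gene_sets[[sprintf("DECOY_X%d", j)]] <-
        sort(sample(genes, cf$extra_set_sizes[[j]]))
    }

    structure(
      list(tfs = tfs, genes = genes, motif_prior = prior, ppi = ppi,
           planted_modules = modules, gene_sets = gene_sets, seed = cf$seed),
      class = "regulatory_truth"
    )
  })
}

#' @export
print.regulatory_truth <- function(x, ...) {
  cat("Regulatory truth:", length(x$tfs), "TFs x", length(x$genes), "genes;",
      sum(x$motif_prior), "prior edges;", length(x$planted_modules),
      "planted modules;", length(x$gene_sets), "gene sets\n")
  invisible(x)
}

#' Configuration for promoter sequence fixtures
#'
#' @param genes Character vector of gene ids (one promoter each) or an
#'   integer count.
#' @param pwms Optional list of [pwm()] objects; if `NULL`, `n_pwms`
#'   information-rich PWMs (`PWM1...`, dominant base probability
#'   `consensus_prob`) are generated.
#' @param n_pwms,pwm_length Used when generating PWMs. The default length of
#'   10 keeps an exact consensus match rarer than 1e-5 under a uniform
#'   background (0.25^10), so planted consensus sites clear the empirical
#'   null cutoff.
#' @param consensus_prob Probability mass on the dominant base per position.
#' @param promoter_length Promoter record length in nt (>= 1001 so the
#'   \[-750, +250\] window fits; the TSS sits at position 751).
#' @param background Named base frequencies (A, C, G, T) summing to 1.
#' @param planted_sites Either an integer count of sites to place at random
#'   (consensus sequence of a random PWM at a random in-window offset and
#'   strand), or a data.frame with columns `gene`, `tf`, `offset`, `strand`.
#' @param seed Integer seed.
#' @return A `seq_config` list.
#' @export
seq_config <- function(genes = 10L, pwms = NULL, n_pwms = 3L, pwm_length = 10L,
                       consensus_prob = 0.97, promoter_length = 1001L,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       planted_sites = 0L, seed = 1L) {
  if (is.numeric(genes) && length(genes) == 1L)
    genes <- sprintf("G%04d", seq_len(genes))
  if (promoter_length < 1001L)
    stop("promoter_length must be >= 1001 so the [-750, +250] window fits")
  if (abs(sum(background) - 1) > 1e-6)
    stop("background frequencies must sum to 1")
  structure(as.list(environment()), class = "seq_config")
}

#' Generate promoter FASTA fixtures with planted PWM sites
#'
#' Draws i.i.d. background sequence for each promoter, then overwrites the
#' PWM consensus (reverse-complemented for minus-strand sites) at the planted
#' offsets inside the \[-750, +250\] window relative to the declared TSS
#' (record position 751). The planted-site table records gene, TF, offset
#' (site start relative to TSS, negative = upstream) and strand.
#'
#' @param config A [seq_config()].
#' @return List with `promoters` (`Biostrings::DNAStringSet`, one record per
#'   gene), `tss` (data.frame `gene`, `tss_pos`, `strand`), `pwms` (list of
#'   [pwm()]), `planted_sites` (data.frame `gene`, `tf`, `offset`, `strand`),
#'   `background`, `seed`.
#' @export
generate_promoter_fixtures <- function(config) {
  stopifnot(inherits(config, "seq_config"))
  cf <- config
  bases <- c("A", "C", "G", "T")
  with_seed(cf$seed, {
    pwms <- cf$pwms
    if (is.null(pwms)) {
      pwms <- lapply(seq_len(cf$n_pwms), function(i) {
        mat <- matrix((1 - cf$consensus_prob) / 3, cf$pwm_length, 4,
                      dimnames = list(NULL, bases))
        dom <- sample.int(4, cf$pwm_length, replace = TRUE)
        mat[cbind(seq_len(cf$pwm_length), dom)] <- cf$consensus_prob
        pwm(sprintf("PWM%d", i), mat)
      })
    }
    names(pwms) <- vapply(pwms, function(p) p$tf_name, character(1))

    n_gene <- length(cf$genes)
    seqs <- vapply(seq_len(n_gene), function(i) {
      paste(sample(bases, cf$promoter_length, replace = TRUE,
                   prob = cf$background), collapse = "")
    }, character(1))
    names(seqs) <- cf$genes
    tss_pos <- 751L

    sites <- cf$planted_sites
    if (is.numeric(sites) && length(sites) == 1L) {
      n_sites <- as.integer(sites)
      sites <- if (n_sites == 0L) {
        data.frame(gene = character(0), tf = character(0),
                   offset = integer(0), strand = character(0))
      } else {
        data.frame(
          gene = sample(cf$genes, n_sites, replace = TRUE),
          tf = sample(names(pwms), n_sites, replace = TRUE),
          offset = NA_integer_, strand = sample(c("+", "-"), n_sites, TRUE),
          stringsAsFactors = FALSE
        )
      }
    }
    sites <- as.data.frame(sites)
    if (nrow(sites) > 0) {
      for (i in seq_len(nrow(sites))) {
        p <- pwms[[sites$tf[i]]]
        if (is.null(p)) stop("planted site references unknown TF: ", sites$tf[i])
        L <- p$length
        if (is.na(sites$offset[i]))
          sites$offset[i] <- sample(seq(-750L, 250L - L), 1L)
        off <- sites$offset[i]
        if (off < -750L || off > 250L - L)
          stop("planted offset outside the promoter window: ", off)
        site_seq <- pwm_consensus(p)
        if (sites$strand[i] == "-")
          site_seq <- .revcomp_string(site_seq)
        start <- tss_pos + off
        s <- seqs[[sites$gene[i]]]
        substr(s, start, start + L - 1L) <- site_seq
        seqs[[sites$gene[i]]] <- s
      }
    }

    list(
      promoters = Biostrings::DNAStringSet(seqs),
      tss = data.frame(gene = cf$genes, tss_pos = tss_pos, strand = "+",
                       stringsAsFactors = FALSE),
      pwms = pwms,
      planted_sites = sites,
      background = cf$background,
      seed = cf$seed
    )
  })
}

.revcomp_string <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
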