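#' Position weight matrix
#'
#' Stores per-position base probabilities for a TF motif. Counts or
#' probabilities are row-normalized, a pseudocount is added (avoiding zero
#' probabilities, hence -Inf log scores) and rows renormalized.
#'
#' @param name TF / motif name.
#' @param matrix Position x 4 numeric matrix of counts or probabilities;
#'   columns in A, C, G, T order (a 4 x L matrix is transposed).
#' @param pseudocount Probability added to every entry before renormalizing.
#' @return Object of class `pwm`: list with `tf_name`, `matrix`
#'   (position x 4 probabilities, each row summing to 1), `length`.
#' @export
pwm <- function(name, matrix, pseudocount = 1e-3) {
  m <- as.matrix(matrix)
  if (ncol(m) != 4L && nrow(m) == 4L) m <- t(m)
  if (ncol(m) != 4L) stop("PWM matrix must have 4 base columns (A, C, G, T)")
  if (any(m < 0) || any(rowSums(m) == 0)) stop("invalid PWM counts")
  m <- m / rowSums(m)
  m <- m + pseudocount
  m <- m / rowSums(m)
  colnames(m) <- c("A", "C", "G", "T")
  if (any(abs(rowSums(m) - 1) > 1e-6)) stop("PWM rows do not sum to 1")
  structure(list(tf_name = name, matrix = m, length = nrow(m)), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$tf_name, "(", x$length, "positions ), consensus",
      pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM (argmax base per position)
#' @param p A [pwm()].
#' @return Character string of length `p$length`.
#' @export
pwm_consensus <- function(p) {
  stopifnot(inherits(p, "pwm"))
  paste(colnames(p$matrix)[apply(p$matrix, 1, which.max)], collapse = "")
}

#' Read JASPAR-style PFM files
#'
#' Accepts the common plain-text layouts: a `>name` header followed by four
#' rows of counts, either bare numbers or the `A [ 1 2 3 ]` bracketed style.
#'
#' @param path File with one or more PFM records.
#' @param pseudocount Passed to [pwm()].
#' @return Named list of [pwm()] objects.
#' @examples
#' pfm <- system.file("extdata", "example_motifs.pfm", package = "dimorphnet")
#' pwms <- read_jaspar_pfm(pfm)
#' pwm_consensus(pwms$MOTIF_A)
#' @export
read_jaspar_pfm <- function(path, pseudocount = 1e-3) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  idx <- grep("^>", lines)
  if (length(idx) == 0) stop("no '>' headers found in ", path)
  out <- list()
  bounds <- c(idx, length(lines) + 1L)
  for (i in seq_along(idx)) {
    name <- sub("^>\\s*", "", lines[idx[i]])
    name <- strsplit(name, "\\s+")[[1]][1]
    block <- lines[(idx[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(block) != 4L) stop("PFM record '", name, "' needs 4 base rows")
    rows <- lapply(block, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("[\\[\\]]", " ", l, perl = TRUE)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("ragged PFM rows for '", name, "'")
    counts <- t(do.call(rbind, rows))  # position x 4
    out[[name]] <- pwm(name, counts, pseudocount = pseudocount)
  }
  out
}

#' Write PWMs as JASPAR-style PFM text
#' @param pwms Named list of [pwm()] objects.
#' @param path Output file.
#' @param digits Rounding for probability output.
#' @export
write_jaspar_pfm <- function(pwms, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$tf_name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(paste0(b, " [ ",
                        paste(round(p$matrix[, b], digits), collapse = " "),
                        " ]"), con)
    }
  }
  invisible(path)
}

# Encode a nucleotide string as integer codes 1..4 (A, C, G, T); anything
# else (N etc.) becomes NA and contributes 0 to scores.
.encode_seq <- function(s) {
  match(strsplit(toupper(s), "")[[1]], c("A", "C", "G", "T"))
}

# position x 4 log2 likelihood-ratio matrix for a pwm vs background freqs
.pwm_logratio <- function(p, background) {
  background <- background / sum(background)
  log2(sweep(p$matrix, 2, background, "/"))
}

#' Log-likelihood-ratio score of a PWM against one sequence window
#'
#' Returns `sum_positions log2(P(base | PWM position) / P(base | background))`.
#' `N` (or any non-ACGT character) contributes 0 at its position.
#'
#' @param window Nucleotide string of length `pwm$length`.
#' @param pwm A [pwm()].
#' @param background Base frequency vector (A, C, G, T), renormalized
#'   internally.
#' @return Numeric score (log2 units).
#' @export
score_pwm_match <- function(window, pwm,
                            background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(inherits(pwm, "pwm"))
  if (nchar(window) == 0L) stop("empty window")
  if (nchar(window) != pwm$length)
    stop("window length ", nchar(window), " != PWM length ", pwm$length)
  lr <- .pwm_logratio(pwm, background)
  code <- .encode_seq(window)
  contrib <- lr[cbind(seq_along(code), code)]
  sum(contrib[!is.na(code)])
}

# Vectorized scoring of all windows of an encoded sequence (integer codes,
# NA = ambiguous base scores 0). Returns numeric(length(code) - L + 1).
.score_all_windows <- function(code, lr) {
  L <- nrow(lr)
  nw <- length(code) - L + 1L
  if (nw < 1L) return(numeric(0))
  scores <- numeric(nw)
  for (l in seq_len(L)) {
    b <- code[l:(l + nw - 1L)]
    contrib <- unname(lr[l, b])
    contrib[is.na(b)] <- 0
    scores <- scores + contrib
  }
  scores
}

#' Calibrate an empirical null score threshold for a PWM
#'
#' Scores `n_samples` random windows -- drawn i.i.d. from background base
#' frequencies, or as random windows of supplied background sequence -- and
#' returns the empirical `1 - p` quantile, i.e. the score a true site must
#' exceed to be called at significance `p`.
#'
#' @param pwm A [pwm()].
#' @param background Either a base-frequency vector (A, C, G, T) or
#'   background sequence(s) (character vector / `DNAStringSet`) to sample
#'   windows from.
#' @param n_samples Number of null windows (default 1e6; a warning is issued
#'   below that, an error below 1e5).
#' @param p Significance level of the threshold.
#' @param seed Integer seed (sampling is deterministic given it).
#' @return Numeric threshold with attributes `p`, `n_samples`, and
#'   `null_scores_sorted` (ascending, for empirical p-value lookup).
#' @export
calibrate_empirical_null <- function(pwm, background, n_samples = 1e6,
                                     p = 1e-5, seed = 1L) {
  stopifnot(inherits(pwm, "pwm"))
  n_samples <- as.integer(n_samples)
  if (n_samples < 1e5) stop("n_samples too small to resolve p = ", p,
                            " (need >= 1e5)")
  if (n_samples < 1e6) warning("n_samples < 1e6; threshold at p = ", p,
                               " is coarsely resolved")
  L <- pwm$length
  scores <- with_seed(seed, {
    if (is.numeric(background)) {
      bg <- background / sum(background)
      lr <- .pwm_logratio(pwm, bg)
      sc <- numeric(n_samples)
      for (l in seq_len(L))
        sc <- sc + unname(lr[l, sample.int(4L, n_samples, replace = TRUE,
                                           prob = bg)])
      sc
    } else {
      seqs <- as.character(background)
      code <- unlist(lapply(seqs, .encode_seq), use.names = FALSE)
      if (length(code) < L) stop("background sequence shorter than the PWM")
      bg <- tabulate(code[!is.na(code)], 4L)
      bg <- bg / sum(bg)
      lr <- .pwm_logratio(pwm, bg)
      starts <- sample.int(length(code) - L + 1L, n_samples, replace = TRUE)
      sc <- numeric(n_samples)
      for (l in seq_len(L)) {
        b <- code[starts + l - 1L]
        contrib <- unname(lr[l, b])
        contrib[is.na(b)] <- 0
        sc <- sc + contrib
      }
      sc
    }
  })
  sorted <- sort(unname(scores))
  thr <- sorted[min(n_samples, max(1L, ceiling((1 - p) * n_samples)))]
  structure(thr, p = p, n_samples = n_samples, null_scores_sorted = sorted)
}

#' Scan promoter windows for PWM sites passing an empirical null
#'
#' For every gene with a promoter sequence and TSS, extracts the
#' \[-750, +250\] window in transcription orientation and scans both strands
#' with each PWM, reporting sites whose score exceeds that PWM's calibrated
#' null threshold at `p_cutoff`. Offsets are the site start relative to the
#' TSS (negative = upstream) in transcription orientation, so valid offsets
#' span `[-750, 250 - motif_length]`.
#'
#' @param promoters Named character vector or `Biostrings::DNAStringSet`,
#'   one record per gene (names = gene ids).
#' @param tss_table `NULL` (TSS assumed at record position 751, plus strand,
#'   the layout written by [generate_promoter_fixtures()]), or a data.frame
#'   with columns `gene`, `tss_pos` (1-based position within the record) and
#'   optionally `strand`.
#' @param pwms List of [pwm()] objects.
#' @param p_cutoff Empirical significance cutoff per window (default 1e-5).
#' @param background Base-frequency vector for the null; `NULL` uses the
#'   observed base composition of the supplied promoters.
#' @param n_null Null windows per PWM for [calibrate_empirical_null()].
#' @param seed Seed for null calibration.
#' @param thresholds Optional named numeric vector of pre-calibrated
#'   thresholds (skips calibration; no empirical p-values reported then).
#' @return data.frame with columns `gene`, `tf`, `offset`, `strand`, `score`,
#'   `p_empirical` (NA when `thresholds` were supplied).
#' @export
scan_promoters <- function(promoters, tss_table = NULL, pwms,
                           p_cutoff = 1e-5, background = NULL,
                           n_null = 1e6, seed = 1L, thresholds = NULL) {
  nm <- names(promoters)
  seqs <- as.character(promoters)
  names(seqs) <- nm
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("promoters must be named by gene id")
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (is.null(tss_table))
    tss_table <- data.frame(gene = names(seqs), tss_pos = 751L, strand = "+",
                            stringsAsFactors = FALSE)
  if (is.null(tss_table$strand)) tss_table$strand <- "+"
  if (length(pwms) == 0)
    return(data.frame(gene = character(0), tf = character(0),
                      offset = integer(0), strand = character(0),
                      score = numeric(0), p_empirical = numeric(0)))

  codes <- lapply(seqs, .encode_seq)
  if (is.null(background)) {
    allc <- unlist(codes, use.names = FALSE)
    background <- tabulate(allc[!is.na(allc)], 4L)
    names(background) <- c("A", "C", "G", "T")
  }
  background <- background / sum(background)

  nulls <- NULL
  if (is.null(thresholds)) {
    nulls <- lapply(seq_along(pwms), function(i)
      calibrate_empirical_null(pwms[[i]], background, n_samples = n_null,
                               p = p_cutoff, seed = child_seed(seed, i)))
    thresholds <- vapply(nulls, as.numeric, numeric(1))
    names(thresholds) <- vapply(pwms, function(p) p$tf_name, character(1))
    names(nulls) <- names(thresholds)
  }

  lrs <- lapply(pwms, .pwm_logratio, background = background)
  names(lrs) <- vapply(pwms, function(p) p$tf_name, character(1))

  res <- list()
  for (gi in seq_len(nrow(tss_table))) {
    g <- tss_table$gene[gi]
    if (!g %in% names(codes)) {
      warning("gene without promoter sequence skipped: ", g)
      next
    }
    code <- codes[[g]]
    tss <- tss_table$tss_pos[gi]
    if (tss_table$strand[gi] == "+") {
      lo <- max(1L, tss - 750L)
      hi <- min(length(code), tss + 250L - 1L)
      win <- code[lo:hi]
      win_off0 <- lo - tss  # offset of window position 1 relative to TSS
    } else {
      lo <- max(1L, tss - 250L + 1L)
      hi <- min(length(code), tss + 750L)
      win <- rev(5L - code[lo:hi])  # reverse complement in integer codes
      win_off0 <- tss - hi
    }
    for (p in pwms) {
      L <- p$length
      lr <- lrs[[p$tf_name]]
      thr <- thresholds[[p$tf_name]]
      fwd <- .score_all_windows(win, lr)
      rev_code <- rev(5L - win)
      rvs <- .score_all_windows(rev_code, lr)
      nw <- length(fwd)
      for (strand in c("+", "-")) {
        sc <- if (strand == "+") fwd else rvs
        hit <- which(sc > thr)
        if (!length(hit)) next
        # map a reverse-strand window index back to forward coordinates
        start_fwd <- if (strand == "+") hit else (nw - hit + 1L)
        off <- win_off0 + start_fwd - 1L
        keep <- off >= -750L & off <= 250L - L
        if (!any(keep)) next
        pe <- NA_real_
        if (!is.null(nulls)) {
          ns <- attr(nulls[[p$tf_name]], "null_scores_sorted")
          pe <- 1 - findInterval(sc[hit][keep] - 1e-12, ns) / length(ns)
        }
        res[[length(res) + 1L]] <- data.frame(
          gene = g, tf = p$tf_name, offset = off[keep], strand = strand,
          score = sc[hit][keep], p_empirical = pe, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res))
    return(data.frame(gene = character(0), tf = character(0),
                      offset = integer(0), strand = character(0),
                      score = numeric(0), p_empirical = numeric(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$gene, out$tf, out$offset), , drop = FALSE]
}

#' Collapse motif sites into a binary TF x gene prior network
#'
#' @param sites data.frame with `gene` and `tf` columns (e.g. from
#'   [scan_promoters()]).
#' @param tfs,genes Ordered id universes for rows and columns.
#' @return TF x gene 0/1 integer matrix; entry 1 iff at least one site links
#'   the pair.
#' @export
build_motif_prior <- function(sites, tfs, genes) {
  if (anyDuplicated(tfs)) stop("duplicate TF names")
  if (anyDuplicated(genes)) stop("duplicate gene names")
  adj <- matrix(0L, length(tfs), length(genes), dimnames = list(tfs, genes))
  if (nrow(sites) > 0) {
    ti <- match(sites$tf, tfs)
    gi <- match(sites$gene, genes)
    keep <- !is.na(ti) & !is.na(gi)
    adj[cbind(ti[keep], gi[keep])] <- 1L
  }
  adj
}
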