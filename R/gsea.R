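#' Signal-to-noise ranking of a two-class table
#'
#' For each entity (gene or TF), computes the signal-to-noise metric
#' `(mu_A - mu_B) / (s_A + s_B)` across the two column classes, with each
#' class standard deviation floored at `0.2 * |mu|` (0.2 when the class mean
#' is 0) -- the floor used by the canonical GSEA tool. Entities are sorted
#' by metric descending, ties broken by id ascending for determinism.
#'
#' @param table Entity x column numeric matrix (expression samples, or
#'   network degrees with one column per network).
#' @param class_labels Vector of length `ncol(table)` with exactly two
#'   distinct values.
#' @param positive_class The class whose higher values give positive
#'   metrics; defaults to the alphabetically first label (so `"F"` before
#'   `"M"`: female-high entities rank top).
#' @return data.frame of class `ranked_list`: `gene`, `metric`, ordered by
#'   decreasing metric.
#' @export
rank_metric <- function(table, class_labels, positive_class = NULL) {
  labs <- as.character(class_labels)
  ul <- sort(unique(labs))
  if (length(ul) != 2L) stop("class_labels must contain exactly two classes")
  positive_class <- positive_class %||% ul[1]
  if (!positive_class %in% ul) stop("unknown positive class")
  a <- table[, labs == positive_class, drop = FALSE]
  b <- table[, labs != positive_class, drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L) stop("each class needs >= 2 columns")
  floor_sd <- function(s, mu) pmax(s, ifelse(mu == 0, 0.2, 0.2 * abs(mu)))
  mu_a <- rowMeans(a)
  mu_b <- rowMeans(b)
  s_a <- floor_sd(sqrt(row_var(a)), mu_a)
  s_b <- floor_sd(sqrt(row_var(b)), mu_b)
  metric <- (mu_a - mu_b) / (s_a + s_b)
  ids <- rownames(table) %||% as.character(seq_len(nrow(table)))
  ord <- order(-metric, ids)
  structure(data.frame(gene = ids[ord], metric = metric[ord],
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list; at a set member ("hit") the running sum gains
#' `|metric|^p / sum_set |metric|^p`, at a miss it loses `1 / (N - N_set)`.
#' The enrichment score is the running-sum value of maximal absolute
#' deviation from zero (signed). When every hit metric is zero the hit
#' increments fall back to `1 / N_set`; when the set covers the whole
#' universe the walk is all hits and ends at 1.
#'
#' @param ranked A [rank_metric()] result (or data.frame with `gene`,
#'   `metric` sorted by decreasing metric).
#' @param gene_set Character vector; must intersect the ranked universe.
#' @param weight_p Metric weight exponent (1 = canonical weighted GSEA).
#' @return List with `es` and `running` (length-N running sum).
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  genes <- ranked$gene
  hit <- genes %in% gene_set
  if (!any(hit)) stop("gene set disjoint from the ranked universe")
  N <- length(genes)
  Nh <- sum(hit)
  w <- abs(ranked$metric)^weight_p
  NR <- sum(w[hit])
  inc <- numeric(N)
  inc[hit] <- if (NR > 0) w[hit] / NR else 1 / Nh
  if (Nh < N) inc[!hit] <- -1 / (N - Nh)
  running <- cumsum(inc)
  es <- running[which.max(abs(running))]
  list(es = es, running = running)
}

# Fast ES from sorted hit positions (equivalent to enrichment_score but
# O(set size) after O(1) lookups); w = |metric|^p over the full ranked list.
# The running sum is piecewise linear and only attains its extrema just
# after a hit (candidate maxima) or just before one (candidate minima), so
# those are the only positions examined. Ties are broken exactly like the
# full walk: largest |deviation|, earliest position.
.es_at_positions <- function(pos, w, N) {
  k <- length(pos)
  wh <- w[pos]
  NR <- sum(wh)
  gain <- if (NR > 0) wh / NR else rep(1 / k, k)
  if (k == N) return(1)
  miss <- 1 / (N - k)
  cg <- cumsum(gain)
  after <- cg - (pos - seq_len(k)) * miss   # running sum just after hit i
  before <- after - gain                    # just before hit i
  ok <- pos > 1L                            # position 0 is not a step
  cand_val <- c(after, before[ok])
  cand_pos <- c(pos, pos[ok] - 1L)
  best <- order(-abs(cand_val), cand_pos)[1]
  cand_val[best]
}

#' Gene-set enrichment analysis with gene-set permutation
#'
#' Ranks entities with [rank_metric()], scores each gene set with the
#' weighted KS statistic, and builds the null by scoring random same-size
#' sets drawn from the ranked universe on the fixed ranked list (gene-set
#' permutation). When all distinct sets of a given size can be enumerated
#' within `n_perm` draws, the null is the exhaustive enumeration, making
#' permutation p-values exact on tiny universes. `NES = ES / mean(|null ES|
#' of matching sign)`; the nominal p is the matching-sign null fraction at
#' least as extreme; FDR follows the NES-ratio procedure stratified by sign;
#' `signed_score` is `-log10(FDR)` for sets enriched toward the positive
#' class (female, by the package convention) and `+log10(FDR)` otherwise,
#' with FDR floored at `1/(n_perm + 1)` so scores stay finite.
#'
#' @inheritParams rank_metric
#' @param gene_sets Named list of gene-id vectors.
#' @param n_perm Null sets per gene-set size.
#' @param seed Integer seed (results are deterministic given it).
#' @param weight_p KS weight exponent.
#' @param min_size,max_size Set-size filter applied after intersection with
#'   the universe.
#' @return data.frame of class `enrichment_result`: `set`, `size`, `es`,
#'   `nes`, `nominal_p`, `fdr_q`, `direction` (class label the set is
#'   enriched toward), `signed_score`; attribute `n_perm`.
#' @export
gsea <- function(table, class_labels, gene_sets, n_perm = 1000L, seed = 1L,
                 weight_p = 1, min_size = 15L, max_size = 500L,
                 positive_class = NULL) {
  ranked <- rank_metric(table, class_labels, positive_class)
  labs <- sort(unique(as.character(class_labels)))
  pos_class <- positive_class %||% labs[1]
  neg_class <- setdiff(labs, pos_class)
  N <- nrow(ranked)
  w <- abs(ranked$metric)^weight_p

  sets <- lapply(gene_sets, function(s) which(ranked$gene %in% s))
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) stop("no gene sets survive the size filter")
  sets <- sets[keep]
  sizes <- sizes[keep]

  null_by_size <- with_seed(seed, {
    out <- list()
    for (s in sort(unique(sizes))) {
      if (s <= N && choose(N, s) <= n_perm) {
        combos <- utils::combn(N, s)
        es0 <- apply(combos, 2L, function(ix) .es_at_positions(ix, w, N))
      } else {
        es0 <- vapply(seq_len(n_perm), function(i)
          .es_at_positions(sort(sample.int(N, s)), w, N), numeric(1))
      }
      out[[as.character(s)]] <- es0
    }
    out
  })

  obs_es <- vapply(sets, function(ix) .es_at_positions(sort(ix), w, N),
                   numeric(1))

  # per-size normalization constants: mean |null ES| of each sign, with a
  # fallback to the overall mean magnitude when a sign stratum is empty
  sign_means <- lapply(null_by_size, function(null) {
    pos <- mean(null[null > 0])
    neg <- mean(abs(null[null < 0]))
    fall <- mean(abs(null))
    if (!is.finite(pos) || pos == 0) pos <- fall
    if (!is.finite(neg) || neg == 0) neg <- fall
    c(pos = pos, neg = neg)
  })
  norm_es <- function(es, sm) ifelse(es >= 0, es / sm[["pos"]], es / sm[["neg"]])

  nes <- numeric(length(sets))
  nominal_p <- numeric(length(sets))
  null_nes_pool <- list()
  for (i in seq_along(sets)) {
    key <- as.character(sizes[i])
    null <- null_by_size[[key]]
    sm <- sign_means[[key]]
    es <- obs_es[i]
    nes[i] <- norm_es(es, sm)
    same <- if (es >= 0) null[null >= 0] else null[null < 0]
    nominal_p[i] <- if (length(same) == 0) 0 else {
      if (es >= 0) mean(same >= es) else mean(same <= es)
    }
    null_nes_pool[[i]] <- norm_es(null, sm)
  }
  pool <- unlist(null_nes_pool, use.names = FALSE)

  fdr_q <- vapply(seq_along(sets), function(i) {
    x <- nes[i]
    if (x >= 0) {
      denom_null <- sum(pool >= 0)
      num <- if (denom_null == 0) 0 else sum(pool >= x) / denom_null
      denom_obs <- sum(nes >= x) / sum(nes >= 0)
    } else {
      denom_null <- sum(pool < 0)
      num <- if (denom_null == 0) 0 else sum(pool <= x) / denom_null
      denom_obs <- sum(nes <= x) / sum(nes < 0)
    }
    min(1, num / denom_obs)
  }, numeric(1))

  direction <- ifelse(obs_es >= 0, pos_class, neg_class)
  out <- data.frame(set = names(sets), size = sizes, es = obs_es, nes = nes,
                    nominal_p = nominal_p, fdr_q = fdr_q,
                    direction = direction, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$signed_score <- signed_significance(out, positive_class = pos_class,
                                          n_perm = n_perm)
  attr(out, "n_perm") <- n_perm
  attr(out, "positive_class") <- pos_class
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Signed -log10(FDR) significance
#'
#' Sets enriched toward the positive class (female, conventionally) get
#' `-log10(FDR)` (positive values); sets enriched toward the other class
#' get `+log10(FDR)` (negative values). FDR is floored at `1/(n_perm + 1)`
#' so a zero permutation FDR stays finite.
#'
#' @param results An [gsea()] result (needs `fdr_q` and `direction`).
#' @param positive_class Label counted as positive; defaults to the
#'   result's stored orientation.
#' @param n_perm Permutation count defining the FDR floor.
#' @return Numeric vector of signed scores, one per set.
#' @export
signed_significance <- function(results, positive_class = NULL,
                                n_perm = NULL) {
  positive_class <- positive_class %||% attr(results, "positive_class")
  n_perm <- n_perm %||% attr(results, "n_perm") %||% 1000L
  q <- pmax(results$fdr_q, 1 / (n_perm + 1))
  ifelse(results$direction == positive_class, -log10(q), log10(q))
}
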