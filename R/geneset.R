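#' Single-sample rank-weighted gene-set score
#'
#' Per sample, genes are ranked by expression in decreasing order and the
#' score is the sum over all rank positions of the difference between the
#' weighted in-set empirical CDF (weights `|rank value|^alpha`, rank value
#' `N` for the top gene down to 1) and the unweighted out-of-set ECDF.
#' With `alpha = 0` the score depends only on within-sample ranks.
#'
#' @param expr an `expr_matrix`.
#' @param gene_set character vector of gene ids; the intersection with the
#'   matrix must be non-empty and a proper subset of all genes.
#' @param alpha rank weighting exponent (default 0.25).
#' @return Named numeric vector, one score per sample.
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.25) {
  stopifnot(inherits(expr, "expr_matrix"))
  genes <- gene_ids(expr)
  set <- intersect(gene_set, genes)
  if (!length(set)) stop("gene set has no genes in common with the matrix")
  if (length(set) == length(genes)) stop("gene set covers all genes; out-set empty")
  N <- length(genes)
  in_set <- genes %in% set
  apply(expr$values, 2, function(x) {
    ord <- order(x, decreasing = TRUE)
    hit <- in_set[ord]
    rank_value <- N:1
    w <- ifelse(hit, abs(rank_value)^alpha, 0)
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!hit) / (N - length(set))
    sum(p_in - p_out)
  })
}

# Signed maximal deviation of the weighted KS running sum for a set given
# by its positions in a decreasing ranking with statistics `stats_sorted`.
.gsea_es <- function(stats_sorted, positions, p = 1) {
  N <- length(stats_sorted)
  k <- length(positions)
  positions <- sort(positions)
  w <- abs(stats_sorted[positions])^p
  if (sum(w) == 0) w <- rep(1, k)  # all-zero stats: fall back to unweighted KS
  cw <- cumsum(w) / sum(w)
  miss_before <- (positions - seq_len(k)) / (N - k)      # misses before each hit
  dev_after <- cw - miss_before                          # running sum just after each hit
  dev_before <- c(0, cw[-k]) - miss_before               # just before each hit
  es_pos <- max(dev_after)
  es_neg <- min(dev_before)
  if (es_pos >= abs(es_neg)) es_pos else es_neg
}

#' Preranked gene-set enrichment with permutation significance
#'
#' Classic weighted Kolmogorov-Smirnov running-sum enrichment on a ranked
#' gene list. The enrichment score (ES) is the signed maximal deviation of
#' the running sum; the null distribution comes from random gene-label
#' permutations (random sets of the same size); NES is ES divided by the
#' mean |null ES| of the same sign, and the permutation p-value is
#' `(1 + #{|null| >= |ES| of the same sign}) / (1 + #same-sign nulls)`.
#'
#' @param ranked_stats named numeric vector, gene-level statistics (any
#'   order; ranked internally, decreasing).
#' @param gene_set character vector of gene ids (proper subset; < 2 members
#'   present triggers a warning and a flagged result).
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @param p running-sum weight exponent (default 1; 0 = unweighted KS).
#' @return List: `es`, `nes`, `p_value`, `n_perm`, `flagged`.
#' @export
preranked_gsea <- function(ranked_stats, gene_set, n_perm = 1000, seed = 1, p = 1) {
  if (is.null(names(ranked_stats))) stop("ranked_stats must be named by gene")
  if (n_perm < 100) stop("n_perm must be >= 100")
  genes <- names(ranked_stats)
  set <- intersect(gene_set, genes)
  flagged <- FALSE
  if (length(set) < 2) {
    warning("gene set has < 2 members in the ranking; result flagged")
    flagged <- TRUE
  }
  if (!length(set)) return(list(es = NA_real_, nes = NA_real_,
                                p_value = NA_real_, n_perm = n_perm,
                                flagged = TRUE))
  if (length(set) == length(genes)) stop("gene set covers all genes")
  ord <- order(ranked_stats, decreasing = TRUE)
  s <- unname(ranked_stats[ord])
  pos <- which(genes[ord] %in% set)
  es <- .gsea_es(s, pos, p)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  k <- length(pos); N <- length(s)
  null_es <- vapply(seq_len(n_perm), function(i)
    .gsea_es(s, sample.int(N, k), p), 0.0)
  same <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  nes <- if (length(same) && mean(abs(same)) > 0) es / mean(abs(same)) else NA_real_
  p_value <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  list(es = es, nes = nes, p_value = p_value, n_perm = n_perm, flagged = flagged)
}

#' Score a whole gene-set collection per sample
#'
#' @param expr an `expr_matrix`.
#' @param collection named list of gene sets (e.g. from [read_gmt()]).
#' @param alpha passed to [ssgsea_score()].
#' @return Matrix, sets x samples.
#' @export
score_collection <- function(expr, collection, alpha = 0.25) {
  out <- t(vapply(collection, function(s) ssgsea_score(expr, s, alpha),
                  numeric(ncol(expr$values))))
  rownames(out) <- names(collection)
  out
}

#' Compare per-set scores between groups
#'
#' Wilcoxon rank-sum test for two groups, Kruskal-Wallis for more; optional
#' Benjamini-Hochberg adjustment across sets.
#'
#' @param scores sets x samples matrix (or a single named numeric vector).
#' @param labels group label per sample.
#' @param adjust apply BH correction across sets (default FALSE).
#' @return data.frame: set, statistic, p_value (and p_adjust if requested).
#' @export
compare_group_scores <- function(scores, labels, adjust = FALSE) {
  if (is.vector(scores)) scores <- matrix(scores, nrow = 1,
                                          dimnames = list("set1", names(scores)))
  labels <- as.factor(labels)
  if (any(table(labels) == 0) || nlevels(labels) < 2)
    stop("need >= 2 non-empty groups")
  res <- t(apply(scores, 1, function(x) {
    if (nlevels(labels) == 2) {
      t <- suppressWarnings(wilcox.test(x ~ labels))
      c(statistic = unname(t$statistic), p_value = t$p.value)
    } else {
      t <- kruskal.test(x ~ labels)
      c(statistic = unname(t$statistic), p_value = t$p.value)
    }
  }))
  out <- data.frame(set = rownames(scores), res, stringsAsFactors = FALSE)
  if (adjust) out$p_adjust <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
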