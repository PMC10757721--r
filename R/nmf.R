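#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative matrix `V` (genes x samples) as `W %*% H` by
#' minimizing the generalized Kullback-Leibler divergence with
#' Lee-Seung/Brunet multiplicative updates. Factors are epsilon-floored so
#' they remain strictly positive; the objective is recorded after every
#' iteration and is non-increasing.
#'
#' @param V non-negative numeric matrix without all-zero rows or columns.
#' @param rank factorization rank, `2 <= rank < min(dim(V))`.
#' @param seed integer seed for the random uniform initialization.
#' @param max_iter iteration cap.
#' @param tol relative objective-change stopping tolerance.
#' @return List of class `nmf_fit`: `W` (genes x rank), `H` (rank x samples),
#'   `rank`, and `objective_trace`.
#' @export
nmf_factorize <- function(V, rank, seed = 1, max_iter = 500, tol = 1e-5) {
  if (!is.matrix(V) || !is.numeric(V)) stop("V must be a numeric matrix")
  if (any(V < 0)) {
    bad <- which(V < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("V has a negative entry at row %d, column %d", bad[1], bad[2]))
  }
  if (any(rowSums(V) == 0) || any(colSums(V) == 0))
    stop("V must have no all-zero rows or columns")
  if (rank < 2 || rank >= min(dim(V)))
    stop("rank out of range: need 2 <= rank < min(dim(V))")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mx <- max(V)
  W0 <- matrix(runif(nrow(V) * rank, 1e-4, mx), nrow(V), rank)
  H0 <- matrix(runif(rank * ncol(V), 1e-4, mx), rank, ncol(V))
  res <- .nmf_kl_cpp(V, W0, H0, as.integer(max_iter), tol, 1e-12)
  dimnames(res$W) <- list(rownames(V), NULL)
  dimnames(res$H) <- list(NULL, colnames(V))
  structure(list(W = res$W, H = res$H, rank = rank,
                 objective_trace = res$objective_trace),
            class = "nmf_fit")
}

#' Connectivity matrix of a clustering
#'
#' @param labels cluster label per sample (named or not).
#' @return Binary symmetric matrix with unit diagonal; entry (i, j) is 1
#'   iff samples i and j share a label.
#' @export
connectivity_matrix <- function(labels) {
  l <- as.vector(labels)
  C <- outer(l, l, "==") * 1
  if (!is.null(names(labels))) dimnames(C) <- list(names(labels), names(labels))
  C
}

#' Consensus NMF over random restarts
#'
#' Runs `n_restarts` factorizations at the given rank from different random
#' initializations, assigns per-restart labels by the argmax of each
#' sample's column of `H`, and averages the restart connectivity matrices
#' into a consensus matrix. Consensus-level labels come from average-linkage
#' hierarchical clustering of `1 - consensus` cut at `rank` clusters.
#' Restarts that leave a cluster empty are discarded with a warning.
#'
#' @param V non-negative matrix (genes x samples).
#' @param rank number of clusters.
#' @param n_restarts number of random restarts (>= 2).
#' @param base_seed integer; restart r uses seed `base_seed + r`.
#' @param max_iter,tol passed to [nmf_factorize()].
#' @return List of class `consensus_result`: `rank`, `consensus`
#'   (samples x samples in [0, 1], symmetric, unit diagonal), `cophenetic`,
#'   `dispersion`, `labels` (integer cluster per sample), `n_restarts_used`.
#' @export
consensus_over_restarts <- function(V, rank, n_restarts = 30, base_seed = 1,
                                    max_iter = 300, tol = 1e-5) {
  if (n_restarts < 2) stop("n_restarts must be >= 2")
  n <- ncol(V)
  acc <- matrix(0, n, n)
  used <- 0L
  for (r in seq_len(n_restarts)) {
    fit <- nmf_factorize(V, rank, seed = base_seed + r, max_iter = max_iter, tol = tol)
    lab <- apply(fit$H, 2, which.max)
    if (length(unique(lab)) < rank) {
      warning("restart ", r, " produced an empty cluster; discarded")
      next
    }
    acc <- acc + connectivity_matrix(lab)
    used <- used + 1L
  }
  if (used == 0L) stop("all restarts degenerate; no consensus available")
  consensus <- acc / used
  dimnames(consensus) <- list(colnames(V), colnames(V))
  hc <- hclust(as.dist(1 - consensus), method = "average")
  labels <- cutree(hc, k = rank)
  structure(list(rank = rank, consensus = consensus,
                 cophenetic = cophenetic_coefficient(consensus),
                 dispersion = dispersion_coefficient(consensus),
                 labels = labels, n_restarts_used = used),
            class = "consensus_result")
}

#' Cophenetic correlation of a consensus matrix
#'
#' Pearson correlation between the cophenetic distances of the
#' average-linkage dendrogram of `1 - consensus` and `1 - consensus` itself.
#' Values near 1 indicate stable clustering. A constant consensus (no
#' dispersion in the distances) is degenerate and returns 0 with a warning.
#'
#' @param consensus symmetric matrix in [0, 1] with unit diagonal.
#' @return A single correlation value.
#' @export
cophenetic_coefficient <- function(consensus) {
  .check_consensus(consensus)
  d <- as.dist(1 - consensus)
  if (sd(d) == 0) {
    warning("constant consensus matrix; cophenetic coefficient undefined, returning 0")
    return(0)
  }
  hc <- hclust(d, method = "average")
  cd <- cophenetic(hc)
  if (sd(cd) == 0) {
    warning("degenerate dendrogram (constant cophenetic distances); returning 0")
    return(0)
  }
  cor(d, cd)
}

#' Dispersion coefficient of a consensus matrix
#'
#' `mean(4 * (consensus - 1/2)^2)`: equals 1 iff every entry is 0 or 1
#' (perfectly reproducible co-clustering) and approaches 0 for entries
#' near 1/2.
#'
#' @param consensus symmetric matrix in [0, 1] with unit diagonal.
#' @return Value in [0, 1].
#' @export
dispersion_coefficient <- function(consensus) {
  .check_consensus(consensus)
  mean(4 * (consensus - 0.5)^2)
}

.check_consensus <- function(consensus) {
  if (!is.matrix(consensus) || nrow(consensus) != ncol(consensus))
    stop("consensus must be a square matrix")
  if (max(abs(consensus - t(consensus))) > 1e-8) stop("consensus must be symmetric")
  if (any(consensus < -1e-12) || any(consensus > 1 + 1e-12))
    stop("consensus entries must lie in [0, 1]")
  if (any(abs(diag(consensus) - 1) > 1e-8)) stop("consensus diagonal must be 1")
  invisible(TRUE)
}

#' Select the factorization rank from cophenetic coefficients
#'
#' Scans ranks in increasing order and returns the largest rank preceding
#' the first strict decrease of the cophenetic coefficient (so the rank at
#' which stability is last still rising or flat). If the coefficients never
#' decrease, the largest rank is returned with a warning.
#'
#' @param cophenetic_by_rank named numeric vector, names are ranks.
#' @return The selected rank (integer).
#' @export
select_rank <- function(cophenetic_by_rank) {
  ranks <- as.integer(names(cophenetic_by_rank))
  if (any(is.na(ranks))) stop("cophenetic_by_rank must be named by rank")
  o <- order(ranks)
  ranks <- ranks[o]; cc <- unname(cophenetic_by_rank[o])
  if (length(ranks) == 1) {
    warning("single rank evaluated; returning it")
    return(ranks)
  }
  drops <- which(diff(cc) < 0)
  if (!length(drops)) {
    warning("cophenetic coefficient never decreases; returning the largest rank")
    return(ranks[length(ranks)])
  }
  ranks[drops[1]]
}

#' Orient a two-cluster labelling as C1/C2
#'
#' Renames the cluster with the higher mean signature-gene expression to
#' "C1" (the efferocytosis-high, poor-prognosis subtype) and the other to
#' "C2". Ties break deterministically toward the cluster containing the
#' first sample. With more than two clusters the labels are returned as
#' "C1".."Ck" in decreasing order of signature expression, with a warning.
#'
#' @param labels cluster ids per sample (named by sample id, or in the
#'   column order of `expr`).
#' @param expr an `expr_matrix`.
#' @param signature character vector of signature gene ids.
#' @return Named character vector of "C1"/"C2" (or "Ck") labels.
#' @export
orient_labels <- function(labels, expr, signature) {
  stopifnot(inherits(expr, "expr_matrix"))
  sids <- if (!is.null(names(labels))) names(labels) else sample_ids(expr)
  sig <- intersect(signature, gene_ids(expr))
  if (!length(sig)) stop("no signature genes present in the expression matrix")
  sig_mean <- colMeans(expr$values[sig, sids, drop = FALSE])
  cl <- sort(unique(as.vector(labels)))
  means <- vapply(cl, function(k) mean(sig_mean[labels == k]), 0.0)
  # decreasing mean; ties resolved toward the first sample's cluster
  first_cl <- labels[[1]]
  ord <- order(-means, cl != first_cl, cl)
  if (length(cl) != 2)
    warning("expected two clusters, got ", length(cl), "; returning Ck names")
  new_names <- paste0("C", seq_along(cl))
  out <- setNames(new_names[match(as.vector(labels), cl[ord])], sids)
  out
}

#' Consensus-NMF subtype discovery
#'
#' End-to-end subtype discovery as used for the efferocytosis subtypes:
#' restrict the expression matrix to the signature genes, run consensus NMF
#' over a grid of ranks, select the rank by the cophenetic rule, and (for
#' rank 2) orient the clusters so C1 is the signature-high subtype.
#'
#' @param expr an `expr_matrix` (TPM values are log2(x+1)-transformed
#'   internally; log2tpm is used as is).
#' @param signature signature gene ids.
#' @param ranks integer vector of ranks to evaluate (default 2:6).
#' @param n_restarts restarts per rank (default 30).
#' @param seed base RNG seed.
#' @param max_iter,tol passed to the factorizer.
#' @return List of class `nmf_subtyping`: `selected_rank`, `labels`
#'   (oriented, named by sample), `per_rank` (list of `consensus_result`),
#'   `cophenetic_by_rank`, `dispersion_by_rank`.
#' @export
nmf_subtype <- function(expr, signature, ranks = 2:6, n_restarts = 30,
                        seed = 1, max_iter = 300, tol = 1e-5) {
  stopifnot(inherits(expr, "expr_matrix"))
  sig <- intersect(signature, gene_ids(expr))
  if (length(sig) < 2) stop("fewer than 2 signature genes found in the matrix")
  V <- expr$values[sig, , drop = FALSE]
  if (expr$unit == "counts") stop("convert counts to TPM before subtyping")
  if (expr$unit == "tpm") V <- log2(V + 1)
  keep <- rowSums(V) > 0
  V <- V[keep, , drop = FALSE]
  per_rank <- lapply(ranks, function(k)
    consensus_over_restarts(V, k, n_restarts = n_restarts,
                            base_seed = seed + 1000L * k,
                            max_iter = max_iter, tol = tol))
  names(per_rank) <- as.character(ranks)
  cc <- vapply(per_rank, function(r) r$cophenetic, 0.0)
  dd <- vapply(per_rank, function(r) r$dispersion, 0.0)
  k_star <- select_rank(cc)
  raw <- per_rank[[as.character(k_star)]]$labels
  labels <- orient_labels(raw, expr, sig)
  structure(list(selected_rank = k_star, labels = labels, per_rank = per_rank,
                 cophenetic_by_rank = cc, dispersion_by_rank = dd),
            class = "nmf_subtyping")
}
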