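# Shared fixtures and independent oracles used across test files.

# small cached cohort so multiple test files can reuse it
.fixture_env <- new.env(parent = emptyenv())
small_cohort <- function(seed = 7, ...) {
  key <- paste0("cohort_", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_cohort(cohort_config(seed = seed, ...))
  .fixture_env[[key]]
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Naive agglomerative average-linkage clustering that records cophenetic
# distances directly from the definition (cluster distance = mean of the
# original pairwise distances across the two clusters). Independent of
# stats::hclust/stats::cophenetic.
naive_cophenetic <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(NA_real_, n, n)
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < best[1]) best <- c(d, i, j)
    }
    i <- best[2]; j <- best[3]
    for (a in clusters[[i]]) for (b in clusters[[j]]) {
      coph[a, b] <- best[1]; coph[b, a] <- best[1]
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  as.dist(coph)
}

# Exhaustive maximal-clique enumeration (subsets of size >= 2) and MCC.
brute_mcc <- function(adj) {
  n <- nrow(adj)
  stopifnot(n <= 14)
  mcc <- numeric(n)
  for (mask in seq_len(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(members) < 2) next
    pairs <- utils::combn(members, 2)
    if (!all(adj[t(pairs)] == 1)) next
    outside <- setdiff(seq_len(n), members)
    maximal <- !any(vapply(outside, function(v) all(adj[v, members] == 1), TRUE))
    if (maximal) mcc[members] <- mcc[members] + factorial(length(members) - 1)
  }
  mcc
}

# Wrap an edge list as an immune_network for hub-scoring tests.
make_network <- function(edges_df) {
  structure(list(nodes = sort(unique(c(edges_df$gene_a, edges_df$gene_b))),
                 edges = edges_df, subtype = NA_character_, ci_threshold = 1),
            class = "immune_network")
}

# Step-by-step GSEA running sum over every position; returns the signed
# maximal deviation (positive branch wins exact ties in magnitude).
es_oracle <- function(stats, set, p = 1) {
  ord <- order(stats, decreasing = TRUE)
  genes <- names(stats)[ord]
  s <- stats[ord]
  hit <- genes %in% set
  N <- length(s); k <- sum(hit)
  w <- abs(s)^p
  if (sum(w[hit]) == 0) w[] <- 1
  steps <- ifelse(hit, w / sum(w[hit]), -1 / (N - k))
  running <- cumsum(steps)
  mx <- max(running); mn <- min(running)
  if (mx >= abs(mn)) mx else mn
}

# Per-position ssGSEA walk (weighted in-set ECDF minus out-set ECDF).
ssgsea_oracle <- function(x, set, alpha = 0.25) {
  ord <- order(x, decreasing = TRUE)
  genes <- names(x)[ord]
  hit <- genes %in% set
  N <- length(x)
  rank_value <- N:1
  total <- 0; cin <- 0; cout <- 0
  win <- sum(abs(rank_value[hit])^alpha)
  for (j in seq_len(N)) {
    if (hit[j]) cin <- cin + abs(rank_value[j])^alpha else cout <- cout + 1
    total <- total + cin / win - cout / (N - sum(hit))
  }
  total
}
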