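#' Discretize expression into per-gene tertiles
#'
#' Per gene, samples are ranked (ties broken by stable sample order) and
#' split into equal thirds: lowest third "low", middle "mid", upper "high".
#' Constant genes cannot be ranked meaningfully and are set to all "mid"
#' with a warning.
#'
#' @param expr an `expr_matrix`.
#' @param genes genes to discretize (default: all); must be present.
#' @return List of class `discretized_matrix`: `categories` (character
#'   matrix, genes x samples, values in low/mid/high), `gene_ids`,
#'   `sample_ids`.
#' @export
discretize_tertiles <- function(expr, genes = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (is.null(genes)) genes <- gene_ids(expr)
  missing <- setdiff(genes, gene_ids(expr))
  if (length(missing)) stop("unknown gene(s): ", paste(missing, collapse = ", "))
  X <- expr$values[genes, , drop = FALSE]
  n <- ncol(X)
  if (n < 3) stop("need at least 3 samples to form tertiles")
  lev <- c("low", "mid", "high")
  cats <- t(apply(X, 1, function(x) {
    if (max(x) == min(x)) return(rep(NA_character_, n))
    lev[ceiling(3 * rank(x, ties.method = "first") / n)]
  }))
  const <- apply(X, 1, function(x) max(x) == min(x))
  if (any(const)) {
    warning(sum(const), " constant gene(s) set to all 'mid': ",
            paste(head(genes[const], 5), collapse = ", "))
    cats[const, ] <- "mid"
  }
  dimnames(cats) <- dimnames(X)
  structure(list(categories = cats, gene_ids = rownames(cats),
                 sample_ids = colnames(cats)),
            class = "discretized_matrix")
}

#' Prevalence filter on discretized expression
#'
#' A gene enters the network only if at least `min_frac` of samples show
#' mid or high expression (default 66%, read literally as >= 0.66).
#'
#' @param disc a `discretized_matrix`.
#' @param min_frac minimum mid-or-high fraction (default 0.66).
#' @return Character vector of admitted gene ids.
#' @export
prevalence_filter <- function(disc, min_frac = 0.66) {
  stopifnot(inherits(disc, "discretized_matrix"))
  frac <- rowMeans(disc$categories != "low")
  disc$gene_ids[frac >= min_frac]
}

#' Candidate edges for the immune-regulation network
#'
#' Restricts a protein-interaction catalog to pairs with at least one
#' endpoint among the ligand/receptor seed genes (the 41 immunomodulatory
#' ligands and receptors in the original analysis) and both endpoints
#' admitted by the prevalence filter. Setting `allow_candidate_candidate`
#' drops the seed-endpoint requirement.
#'
#' @param catalog data.frame with columns `gene_a`, `gene_b`.
#' @param seed_genes ligand/receptor seed list.
#' @param admitted genes passing [prevalence_filter()].
#' @param allow_candidate_candidate also keep pairs between two non-seed
#'   genes (default FALSE).
#' @return The filtered catalog (possibly empty, with a warning).
#' @export
candidate_edges <- function(catalog, seed_genes, admitted,
                            allow_candidate_candidate = FALSE) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(catalog)))
  if (!length(seed_genes)) stop("seed_genes must be non-empty")
  if (any(catalog$gene_a == catalog$gene_b)) stop("catalog contains self-loops")
  keep_seed <- allow_candidate_candidate |
    catalog$gene_a %in% seed_genes | catalog$gene_b %in% seed_genes
  keep_adm <- catalog$gene_a %in% admitted & catalog$gene_b %in% admitted
  out <- catalog[keep_seed & keep_adm, , drop = FALSE]
  key <- apply(out[, c("gene_a", "gene_b")], 1, function(r) paste(sort(r), collapse = "|"))
  out <- out[!duplicated(key), , drop = FALSE]
  if (!nrow(out)) warning("no candidate edges remain after filtering")
  rownames(out) <- NULL
  out
}

#' Concordance index of a discretized gene pair
#'
#' Over the given samples, counts joint tertile categories of the two genes
#' and computes `(n_HH + n_LL) / (n_LH + n_HL)`. Samples where either gene
#' is "mid" contribute to no count. A zero denominator with a positive
#' numerator yields `Inf` (perfect concordance, strongest possible edge);
#' 0/0 yields 0 with a warning (no informative sample pairs, edge dropped).
#'
#' @param disc a `discretized_matrix`.
#' @param gene_a,gene_b gene ids.
#' @param sample_subset sample ids to use (default: all).
#' @return List: `ci`, `counts` (named: n_HH, n_LL, n_LH, n_HL).
#' @export
concordance_index <- function(disc, gene_a, gene_b, sample_subset = NULL) {
  stopifnot(inherits(disc, "discretized_matrix"))
  for (g in c(gene_a, gene_b))
    if (!g %in% disc$gene_ids) stop("unknown gene: ", g)
  if (is.null(sample_subset)) sample_subset <- disc$sample_ids
  if (!length(sample_subset)) stop("sample subset is empty")
  a <- disc$categories[gene_a, sample_subset]
  b <- disc$categories[gene_b, sample_subset]
  counts <- c(n_HH = sum(a == "high" & b == "high"),
              n_LL = sum(a == "low" & b == "low"),
              n_LH = sum(a == "low" & b == "high"),
              n_HL = sum(a == "high" & b == "low"))
  num <- counts[["n_HH"]] + counts[["n_LL"]]
  den <- counts[["n_LH"]] + counts[["n_HL"]]
  ci <- if (den == 0) {
    if (num == 0) {
      warning("no concordant or discordant samples for pair ",
              gene_a, "-", gene_b, "; concordance index set to 0")
      0
    } else Inf
  } else num / den
  list(ci = ci, counts = counts)
}

#' Build the subtype immune-regulation network
#'
#' Scores every candidate pair by its concordance index over the given
#' sample subset (one subtype's samples), keeps edges with
#' `ci > ci_threshold` (strict, default 1), and removes isolated nodes.
#'
#' @param disc a `discretized_matrix` computed on the same sample subset.
#' @param candidates data.frame of candidate pairs (`gene_a`, `gene_b`).
#' @param sample_subset sample ids (default: all in `disc`).
#' @param ci_threshold concordance-index cutoff (default 1).
#' @param subtype optional label stored with the network.
#' @return List of class `immune_network`: `nodes`, `edges` (data.frame with
#'   gene_a, gene_b, n_HH, n_LL, n_LH, n_HL, ci), `subtype`.
#' @export
build_network <- function(disc, candidates, sample_subset = NULL,
                          ci_threshold = 1, subtype = NA_character_) {
  stopifnot(inherits(disc, "discretized_matrix"))
  if (!nrow(candidates)) stop("candidates must be non-empty")
  res <- lapply(seq_len(nrow(candidates)), function(i) {
    r <- concordance_index(disc, candidates$gene_a[i], candidates$gene_b[i],
                           sample_subset)
    c(r$counts, ci = unname(r$ci))
  })
  edges <- cbind(candidates[, c("gene_a", "gene_b")],
                 as.data.frame(do.call(rbind, res)))
  edges <- edges[edges$ci > ci_threshold, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  if (!nrow(edges)) message("empty network: no edge exceeded ci_threshold = ", ci_threshold)
  structure(list(nodes = nodes, edges = edges, subtype = subtype,
                 ci_threshold = ci_threshold),
            class = "immune_network")
}

#' @export
print.immune_network <- function(x, ...) {
  cat(sprintf("<immune_network> %d nodes, %d edges (ci > %g)%s\n",
              length(x$nodes), nrow(x$edges), x$ci_threshold,
              if (is.na(x$subtype)) "" else paste0(", subtype ", x$subtype)))
  invisible(x)
}

.network_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges[, c("gene_a", "gene_b")],
                                directed = FALSE,
                                vertices = data.frame(name = network$nodes))
}

#' Maximal-clique-centrality and degree hub scores
#'
#' MCC(v) is the sum of `(|C| - 1)!` over all maximal cliques C containing
#' v (maximal cliques enumerated by Bron-Kerbosch with pivoting via
#' igraph). Every node of a pruned network sits in at least one maximal
#' clique of size >= 2, so `MCC(v) >= degree-derived lower bound of 1 per
#' incident edge's clique`.
#'
#' @param network an `immune_network` (or any simple undirected graph given
#'   as one).
#' @param max_nodes clique-enumeration budget; larger graphs are refused
#'   with advice to analyze a subgraph.
#' @return List of class `hub_result`: `scores` data.frame (gene, mcc,
#'   degree) sorted by (mcc desc, gene).
#' @export
mcc_scores <- function(network, max_nodes = 5000) {
  stopifnot(inherits(network, "immune_network"))
  if (length(network$nodes) > max_nodes)
    stop("graph exceeds the clique-enumeration budget (", max_nodes,
         " nodes); analyze a subgraph")
  g <- .network_igraph(network)
  cliques <- igraph::max_cliques(g, min = 2)
  mcc <- setNames(numeric(length(network$nodes)), network$nodes)
  for (cl in cliques) {
    w <- factorial(length(cl) - 1)
    nm <- igraph::V(g)$name[as.integer(cl)]
    mcc[nm] <- mcc[nm] + w
  }
  deg <- igraph::degree(g)[network$nodes]
  scores <- data.frame(gene = network$nodes, mcc = unname(mcc),
                       degree = unname(deg), stringsAsFactors = FALSE)
  scores <- scores[order(-scores$mcc, scores$gene), ]
  rownames(scores) <- NULL
  structure(list(scores = scores), class = "hub_result")
}

#' Hub genes by intersecting MCC and Degree top lists
#'
#' Takes the top `top_k` genes by MCC and by degree (score ties at rank
#' `top_k` expand the top set) and returns their intersection, ordered by
#' (MCC score desc, gene id).
#'
#' @param network an `immune_network`.
#' @param top_k size of each top list before intersecting (default 10).
#' @return Character vector of hub gene ids (possibly empty).
#' @export
hub_intersection <- function(network, top_k = 10) {
  hr <- mcc_scores(network)
  sc <- hr$scores
  top_by <- function(v) {
    if (!length(v)) return(character(0))
    ord <- order(-v, sc$gene)
    k <- min(top_k, length(v))
    cutoff <- v[ord][k]
    sc$gene[v >= cutoff]  # ties at the boundary expand the set
  }
  hubs <- intersect(top_by(sc$mcc), top_by(sc$degree))
  hubs[order(-sc$mcc[match(hubs, sc$gene)], hubs)]
}
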