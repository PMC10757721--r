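disc_from_matrix <- function(m) {
  discretize_tertiles(expr_matrix(m, "tpm"))
}

test_that("tertile discretization splits ranks into equal thirds", {
  m <- matrix(c(9:1, rep(5, 9)), 2, 9, byrow = TRUE,
              dimnames = list(c("g1", "gconst"), sprintf("s%d", 1:9)))
  expect_warning(d <- disc_from_matrix(m), "constant")
  expect_equal(as.vector(table(d$categories["g1", ])[c("low", "mid", "high")]),
               c(3L, 3L, 3L))
  expect_true(all(d$categories["gconst", ] == "mid"))
  expect_true(all(d$categories %in% c("low", "mid", "high")))
  # decreasing values map low ranks to 'low'
  expect_equal(unname(d$categories["g1", c("s1", "s9")]), c("high", "low"))
  tiny <- matrix(1:2, 1, 2, dimnames = list("g", c("a", "b")))
  expect_error(disc_from_matrix(tiny), "3 samples")
})

test_that("prevalence filter admits genes at >= 66% mid-or-high", {
  mk <- function(n_low, n) {
    m <- matrix(seq_len(n), 1, n, dimnames = list("g", sprintf("s%d", 1:n)))
    d <- disc_from_matrix(m)
    # overwrite categories to the target composition
    d$categories[1, ] <- c(rep("low", n_low), rep("high", n - n_low))
    d
  }
  expect_equal(prevalence_filter(mk(3, 10)), "g")      # 7/10
  expect_equal(prevalence_filter(mk(4, 10)), character(0))  # 6/10
  expect_equal(prevalence_filter(mk(34, 100)), "g")    # exactly 66/100
  expect_equal(prevalence_filter(mk(35, 100)), character(0))
})

test_that("candidate edges need a seed endpoint and two admitted endpoints", {
  cat <- data.frame(gene_a = c("L1", "L1", "x", "L2"),
                    gene_b = c("p1", "p2", "y", "p3"))
  out <- candidate_edges(cat, seed_genes = c("L1", "L2"),
                         admitted = c("L1", "L2", "p1", "p3", "x", "y"))
  expect_equal(out$gene_b, c("p1", "p3"))  # p2 unadmitted, x-y has no seed
  out2 <- candidate_edges(cat, c("L1", "L2"),
                          admitted = c("L1", "L2", "p1", "p3", "x", "y"),
                          allow_candidate_candidate = TRUE)
  expect_equal(nrow(out2), 3)
  expect_warning(candidate_edges(cat, "L9", admitted = "L9"), "no candidate")
})

test_that("concordance index matches direct counting including degenerate cases", {
  build_disc <- function(a, b) {
    n <- length(a)
    d <- disc_from_matrix(matrix(rep(seq_len(n), 2), 2, n, byrow = TRUE,
                                 dimnames = list(c("ga", "gb"),
                                                 sprintf("s%d", 1:n))))
    d$categories["ga", ] <- a; d$categories["gb", ] <- b
    d
  }
  a <- c(rep("high", 10), rep("low", 10), rep("low", 5), rep("high", 5))
  b <- c(rep("high", 10), rep("low", 10), rep("high", 5), rep("low", 5))
  r <- concordance_index(build_disc(a, b), "ga", "gb")
  expect_equal(r$ci, 2.0)
  expect_equal(unname(r$counts), c(10L, 10L, 5L, 5L))
  # pure discordance
  r0 <- concordance_index(build_disc(c("low", "low", "high", "high", "mid"),
                                     c("high", "high", "low", "low", "mid")),
                          "ga", "gb")
  expect_equal(r0$ci, 0.0)
  # perfect concordance with no discordant pair
  rInf <- concordance_index(build_disc(rep("high", 4), rep("high", 4)), "ga", "gb")
  expect_equal(rInf$ci, Inf)
  # all-mid: 0/0 policy
  expect_warning(
    rz <- concordance_index(build_disc(rep("mid", 4), rep("mid", 4)), "ga", "gb"),
    "set to 0")
  expect_equal(rz$ci, 0)
  expect_error(concordance_index(build_disc(a, b), "ga", "nope"), "unknown gene")
})

test_that("concordance index is symmetric and invariant to monotone transforms", {
  set.seed(6)
  ch <- small_cohort(n_samples = 90, n_genes = 60, n_signature_genes = 10,
                     n_lr_pairs = 4)
  ex <- ch$expression
  d1 <- discretize_tertiles(ex)
  ex2 <- expr_matrix(log2(ex$values + 1)^3, "tpm")  # strictly monotone transform
  d2 <- discretize_tertiles(ex2)
  for (i in 1:10) {
    gs <- sample(gene_ids(ex), 2)
    r_ab <- concordance_index(d1, gs[1], gs[2])
    r_ba <- concordance_index(d1, gs[2], gs[1])
    expect_equal(r_ab$ci, r_ba$ci)
    expect_equal(r_ab$ci, concordance_index(d2, gs[1], gs[2])$ci)
  }
})

test_that("network building keeps concordant planted pairs and prunes failed nodes", {
  ch <- small_cohort(n_samples = 300, n_genes = 80, n_signature_genes = 10,
                     n_lr_pairs = 5, lr_coupling = 1)
  c1 <- names(ch$truth_labels)[ch$truth_labels == "C1"]
  ex <- subset_expr(log2_tpm(ch$expression), samples = c1)
  net_genes <- unique(c(ch$interaction_catalog$gene_a, ch$interaction_catalog$gene_b))
  disc <- discretize_tertiles(ex, net_genes)
  cand <- candidate_edges(ch$interaction_catalog, ch$lr_seed_genes,
                          prevalence_filter(disc))
  net <- build_network(disc, cand, subtype = "C1")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  got <- key(net$edges$gene_a, net$edges$gene_b)
  planted <- key(ch$planted_edges$gene_a, ch$planted_edges$gene_b)
  expect_true(all(planted %in% got))  # perfectly coupled pairs always survive
  # every node has degree >= 1 and every edge endpoint is a node
  expect_setequal(net$nodes, unique(c(net$edges$gene_a, net$edges$gene_b)))
  # an anti-concordant pair is excluded
  flip <- ex
  g_dec <- setdiff(net_genes, c(ch$planted_edges$gene_a, ch$planted_edges$gene_b))[1]
  flip$values[g_dec, ] <- max(flip$values) - flip$values[ch$planted_edges$gene_a[1], ]
  d2 <- discretize_tertiles(flip, net_genes)
  anti <- data.frame(gene_a = ch$planted_edges$gene_a[1], gene_b = g_dec)
  net2 <- suppressMessages(build_network(d2, anti))
  expect_equal(nrow(net2$edges), 0)
  expect_length(net2$nodes, 0)
})

test_that("MCC matches exhaustive maximal-clique enumeration", {
  # triangle: every node in one 3-clique
  tri <- make_network(data.frame(gene_a = c("a", "b", "a"),
                                 gene_b = c("b", "c", "c")))
  sc <- mcc_scores(tri)$scores
  expect_equal(sc$mcc, rep(2, 3))
  # path a-b-c
  path <- make_network(data.frame(gene_a = c("a", "b"), gene_b = c("b", "c")))
  sp <- mcc_scores(path)$scores
  expect_equal(sp$mcc[sp$gene == "b"], 2)
  expect_equal(sp$mcc[sp$gene %in% c("a", "c")], c(1, 1))
  # random graphs vs the exponential oracle
  set.seed(12)
  for (i in 1:15) {
    n <- sample(4:10, 1)
    adj <- matrix(0L, n, n)
    adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, 0.45)
    adj <- adj + t(adj)
    nodes <- sprintf("v%02d", 1:n)
    dimnames(adj) <- list(nodes, nodes)
    ew <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
    if (!nrow(ew)) next
    net <- make_network(data.frame(gene_a = nodes[ew[, 1]], gene_b = nodes[ew[, 2]]))
    keep <- rowSums(adj) > 0  # isolated nodes are pruned before scoring
    sc <- mcc_scores(net)$scores
    oracle <- brute_mcc(adj)[keep]
    expect_equal(sc$mcc[match(nodes[keep], sc$gene)], oracle)
    expect_equal(sc$degree[match(nodes[keep], sc$gene)],
                 unname(rowSums(adj)[keep]))
    # each incident edge contributes at least 1 through some maximal clique
    expect_true(all(sc$mcc >= 1))
  }
  expect_error(mcc_scores(tri, max_nodes = 2), "budget")
})

test_that("hub intersection honours top-k ties and ordering", {
  # star plus triangle: hub ranking identical for MCC and degree
  net <- make_network(data.frame(
    gene_a = c("h", "h", "h", "h", "a", "a"),
    gene_b = c("a", "b", "c", "d", "b", "e")))
  hubs <- hub_intersection(net, top_k = 2)
  expect_equal(hubs[1], "h")
  # disjoint top sets produce an empty intersection
  hr <- mcc_scores(net)$scores
  expect_true(all(hub_intersection(net, top_k = nrow(hr)) %in% hr$gene))
  # tie at the boundary expands the set: all leaves tie at degree 1
  line <- make_network(data.frame(gene_a = c("a", "b", "c"),
                                  gene_b = c("b", "c", "d")))
  hubs2 <- hub_intersection(line, top_k = 1)
  expect_setequal(hubs2, c("b", "c"))  # both middle nodes tie
})
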