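test_that("factorization reconstructs an exact low-rank product and never increases the objective", {
  set.seed(3)
  W0 <- matrix(runif(30 * 2, 0.5, 2), 30, 2)
  H0 <- matrix(runif(2 * 20, 0.5, 2), 2, 20)
  V <- W0 %*% H0
  dimnames(V) <- list(sprintf("g%d", 1:30), sprintf("s%d", 1:20))
  fit <- nmf_factorize(V, 2, seed = 1, max_iter = 3000, tol = 0)
  expect_lt(fit$objective_trace[length(fit$objective_trace)], 1e-6 * sum(V))
  expect_true(all(diff(fit$objective_trace) <=
                    1e-8 * (1 + abs(fit$objective_trace[-length(fit$objective_trace)]))))
  expect_true(all(fit$W > 0) && all(fit$H > 0))
  # objective also monotone on noisy data
  Vn <- V + matrix(runif(length(V), 0, 0.5), nrow(V))
  fit2 <- nmf_factorize(Vn, 3, seed = 2, max_iter = 200, tol = 0)
  expect_true(all(diff(fit2$objective_trace) <=
                    1e-8 * (1 + abs(fit2$objective_trace[-length(fit2$objective_trace)]))))
  # invalid inputs
  Vbad <- V; Vbad[2, 3] <- -1
  expect_error(nmf_factorize(Vbad, 2), "negative")
  expect_error(nmf_factorize(V, 25), "rank out of range")
})

test_that("connectivity matrices encode co-membership", {
  C <- connectivity_matrix(c(1, 1, 2))
  expect_equal(C, rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)))
  expect_equal(connectivity_matrix(rep("a", 4)), matrix(1, 4, 4))
  expect_equal(connectivity_matrix(1:3), diag(3))
})

test_that("consensus over restarts is a valid co-clustering average with block structure", {
  ch <- small_cohort(n_samples = 60, n_genes = 90, n_signature_genes = 30,
                     signature_effect = 2)
  V <- log2(ch$expression$values[ch$signature_genes, ] + 1)
  cr <- consensus_over_restarts(V, 2, n_restarts = 8, base_seed = 1,
                                max_iter = 150, tol = 1e-4)
  expect_true(all(cr$consensus >= 0 & cr$consensus <= 1))
  expect_equal(unname(diag(cr$consensus)), rep(1, ncol(V)))
  expect_equal(cr$consensus, t(cr$consensus))
  # strong effect: near-binary block structure aligned with truth
  same <- outer(ch$truth_labels, ch$truth_labels, "==")
  expect_gt(mean(cr$consensus[same]), 0.95)
  expect_lt(mean(cr$consensus[!same]), 0.05)
  expect_gte(ari(cr$labels, ch$truth_labels), 0.9)
})

test_that("cophenetic coefficient matches a from-definition average-linkage oracle", {
  # ideal two-block consensus is a perfect ultrametric
  C <- matrix(0, 6, 6); C[1:3, 1:3] <- 1; C[4:6, 4:6] <- 1
  expect_equal(cophenetic_coefficient(C), 1.0)
  # random symmetric consensus vs naive oracle
  set.seed(9)
  for (i in 1:5) {
    M <- matrix(runif(36), 6, 6); M <- (M + t(M)) / 2; diag(M) <- 1
    d <- as.dist(1 - M)
    expect_equal(cophenetic_coefficient(M), cor(d, naive_cophenetic(d)),
                 tolerance = 1e-10)
  }
  # constant consensus is degenerate
  C5 <- matrix(0.5, 4, 4); diag(C5) <- 1
  Cc <- matrix(1, 4, 4)
  expect_warning(v <- cophenetic_coefficient(Cc), "constant")
  expect_equal(v, 0)
})

test_that("dispersion is 1 on binary consensus and follows its closed form", {
  C <- matrix(0, 5, 5); C[1:2, 1:2] <- 1; C[3:5, 3:5] <- 1
  expect_equal(dispersion_coefficient(C), 1.0)
  n <- 6
  Ch <- matrix(0.5, n, n); diag(Ch) <- 1
  expect_equal(dispersion_coefficient(Ch), n / n^2)  # only the unit diagonal contributes
  set.seed(2)
  M <- matrix(runif(16), 4, 4); M <- (M + t(M)) / 2; diag(M) <- 1
  v <- dispersion_coefficient(M)
  expect_true(v >= 0 && v <= 1)
})

test_that("rank selection stops before the first cophenetic drop", {
  expect_equal(select_rank(c(`2` = 0.99, `3` = 0.95, `4` = 0.96)), 2)
  expect_equal(select_rank(c(`2` = 0.90, `3` = 0.95, `4` = 0.93)), 3)
  expect_warning(k <- select_rank(c(`2` = 0.5, `3` = 0.6, `4` = 0.7, `5` = 0.8, `6` = 0.9)),
                 "never decreases")
  expect_equal(k, 6)
  expect_warning(k1 <- select_rank(c(`3` = 0.8)), "single rank")
  expect_equal(k1, 3)
})

test_that("cluster orientation is signature-driven and invariant to label permutation", {
  ch <- small_cohort(n_samples = 60, n_genes = 90, n_signature_genes = 30,
                     signature_effect = 2)
  expr <- log2_tpm(ch$expression)
  truth_codes <- ifelse(ch$truth_labels == "C1", 1, 2)
  o1 <- orient_labels(truth_codes, expr, ch$signature_genes)
  o2 <- orient_labels(3 - truth_codes, expr, ch$signature_genes)  # swapped ids
  expect_identical(o1, o2)
  expect_gte(ari(o1, ch$truth_labels), 0.99)
  expect_identical(unname(o1), unname(ch$truth_labels[names(o1)]))
  expect_warning(orient_labels(rep(1:3, 20), expr, ch$signature_genes),
                 "two clusters")
})

test_that("end-to-end subtype discovery recovers the planted two-subtype structure", {
  ch <- small_cohort()
  st <- nmf_subtype(log2_tpm(ch$expression), ch$signature_genes, ranks = 2:3,
                    n_restarts = 8, seed = 7, max_iter = 150, tol = 1e-4)
  expect_equal(st$selected_rank, 2)
  expect_gte(ari(st$labels, ch$truth_labels[names(st$labels)]), 0.9)
  # C1 is the signature-high subtype
  sig_mean <- colMeans(log2_tpm(ch$expression)$values[ch$signature_genes, ])
  expect_gt(mean(sig_mean[st$labels == "C1"]), mean(sig_mean[st$labels == "C2"]))
})
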