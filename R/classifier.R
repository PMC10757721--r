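#' Fit a nearest-shrunken-centroid subtype classifier
#'
#' The "PAM" (prediction analysis for microarrays) classifier used to
#' transfer discovered subtype labels onto new cohorts. Per gene i and
#' class k the standardized centroid deviation is
#' `d_ik = (xbar_ik - xbar_i) / (m_k * (s_i + s0))` with
#' `m_k = sqrt(1/n_k - 1/n)`, `s_i` the pooled within-class SD and
#' `s0 = median(s_i)`; deviations are soft-thresholded by `delta` and the
#' shrunken centroids are `xbar_i + m_k * (s_i + s0) * d'_ik`. `delta` is
#' chosen from `delta_grid` by stratified cross-validated accuracy, ties
#' resolved toward the larger (sparser) `delta`.
#'
#' @param expr an `expr_matrix` (typically log2 TPM of signature genes).
#' @param labels class label per sample, named by sample id or in column
#'   order.
#' @param delta_grid non-negative shrinkage values to tune over.
#' @param cv_folds number of stratified folds (default 5).
#' @param seed RNG seed for fold assignment.
#' @return List of class `centroid_model`: `gene_ids`, `classes`, `priors`,
#'   `overall_centroid`, `class_centroids`, `shrunken_centroids`, `s`, `s0`,
#'   `delta`, `unit`, `cv_accuracy` (per delta).
#' @export
fit_centroid_classifier <- function(expr, labels,
                                    delta_grid = seq(0, 3, by = 0.5),
                                    cv_folds = 5, seed = 1) {
  stopifnot(inherits(expr, "expr_matrix"))
  X <- expr$values
  sids <- colnames(X)
  if (!is.null(names(labels))) labels <- labels[sids]
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 classes")
  if (any(tab < 2))
    stop("class(es) with < 2 samples: ", paste(names(tab)[tab < 2], collapse = ", "))
  if (any(tab < cv_folds)) {
    cv_folds <- max(2L, min(tab))
    warning("cv_folds reduced to ", cv_folds, " (smallest class size)")
  }
  if (any(delta_grid < 0)) stop("delta_grid must be non-negative")

  cv_acc <- setNames(numeric(length(delta_grid)), as.character(delta_grid))
  if (length(delta_grid) > 1) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    fold <- integer(length(labels))
    for (k in unique(labels)) {
      idx <- which(labels == k)
      fold[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
    }
    correct <- matrix(0, length(delta_grid), 1)
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      fit_f <- .nsc_fit(X[, tr, drop = FALSE], labels[tr])
      for (di in seq_along(delta_grid)) {
        m <- .nsc_shrink(fit_f, delta_grid[di])
        pred <- .nsc_predict(m, X[, !tr, drop = FALSE])$label
        correct[di] <- correct[di] + sum(pred == labels[!tr])
      }
    }
    cv_acc[] <- correct / length(labels)
    best <- max(cv_acc)
    delta <- max(delta_grid[cv_acc >= best - 1e-12])
  } else {
    delta <- delta_grid[1]
    cv_acc[] <- NA_real_
  }

  fit <- .nsc_fit(X, labels)
  model <- .nsc_shrink(fit, delta)
  model$cv_accuracy <- cv_acc
  model$unit <- expr$unit
  class(model) <- "centroid_model"
  model
}

# Unshrunk sufficient statistics for the NSC classifier.
.nsc_fit <- function(X, labels) {
  classes <- sort(unique(labels))
  n <- ncol(X)
  xbar <- rowMeans(X)
  cent <- sapply(classes, function(k) rowMeans(X[, labels == k, drop = FALSE]))
  nk <- vapply(classes, function(k) sum(labels == k), 0L)
  ss <- rowSums(sapply(classes, function(k) {
    d <- X[, labels == k, drop = FALSE] - cent[, k]
    rowSums(d^2)
  }))
  s <- sqrt(ss / (n - length(classes)))
  list(gene_ids = rownames(X), classes = classes, nk = nk, n = n,
       priors = nk / n, overall_centroid = xbar, class_centroids = cent,
       s = s, s0 = median(s), m = sqrt(1 / nk - 1 / n))
}

# Soft-threshold the deviations at a given delta and rebuild centroids.
.nsc_shrink <- function(fit, delta) {
  denom <- outer(fit$s + fit$s0, fit$m)
  d <- (fit$class_centroids - fit$overall_centroid) / denom
  d_shr <- sign(d) * pmax(abs(d) - delta, 0)
  shrunken <- fit$overall_centroid + denom * d_shr
  dimnames(shrunken) <- list(fit$gene_ids, fit$classes)
  c(fit[c("gene_ids", "classes", "priors", "overall_centroid",
          "class_centroids", "s", "s0")],
    list(delta = delta, shrunken_centroids = shrunken,
         shrunken_deviation = d_shr,
         active_genes = fit$gene_ids[rowSums(abs(d_shr) > 0) > 0]))
}

.nsc_predict <- function(model, X) {
  sd2 <- (model$s + model$s0)^2
  delta_k <- sapply(seq_along(model$classes), function(k) {
    colSums((X - model$shrunken_centroids[, k])^2 / sd2) - 2 * log(model$priors[k])
  })
  if (is.null(dim(delta_k))) delta_k <- matrix(delta_k, nrow = 1)
  colnames(delta_k) <- model$classes
  ties <- apply(delta_k, 1, function(r) sum(abs(r - min(r)) < 1e-12) > 1)
  if (any(ties))
    warning(sum(ties), " sample(s) with tied discriminant scores; ",
            "assigned to the lexicographically first class")
  label <- model$classes[apply(delta_k, 1, which.min)]
  # posterior-style scores: softmax of -delta/2
  sc <- exp(-(delta_k - apply(delta_k, 1, min)) / 2)
  sc <- sc / rowSums(sc)
  list(label = setNames(label, colnames(X)), scores = sc,
       discriminant = delta_k)
}

#' Predict subtypes with a fitted centroid model
#'
#' Assigns each sample to the class minimizing the shrunken-centroid
#' discriminant score
#' `delta_k(x) = sum_i (x_i - xbar'_ik)^2 / (s_i + s0)^2 - 2 log pi_k`,
#' and returns softmax posterior-style scores for ROC analysis. Tied scores
#' break toward the lexicographically first class with a warning.
#'
#' @param model a `centroid_model`.
#' @param expr an `expr_matrix` containing every model gene; its unit must
#'   match the training unit.
#' @return List: `label` (named per sample), `scores` (samples x classes
#'   matrix; the "C1" column is the continuous C1-score), `discriminant`.
#' @export
predict_subtype <- function(model, expr) {
  stopifnot(inherits(model, "centroid_model"), inherits(expr, "expr_matrix"))
  if (!is.null(model$unit) && expr$unit != model$unit)
    stop("expression unit '", expr$unit, "' does not match training unit '",
         model$unit, "'")
  missing <- setdiff(model$gene_ids, gene_ids(expr))
  if (length(missing))
    stop("model genes missing from matrix: ", paste(missing, collapse = ", "))
  X <- expr$values[model$gene_ids, , drop = FALSE]
  .nsc_predict(model, X)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' positive outranks a randomly chosen negative, with ties counted 1/2.
#'
#' @param scores numeric scores (higher = more positive).
#' @param truth_binary logical or 0/1 vector; both classes must be present.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, truth_binary) {
  y <- as.logical(truth_binary)
  if (anyNA(y) || anyNA(scores)) stop("missing values in scores or truth")
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' k-medoids-style nearest-medoid assignment
#'
#' The literal "partitioning around medoids" reading of PAM: each class is
#' represented by its training medoid (the sample minimizing total
#' within-class Euclidean distance) and new samples take the label of the
#' nearest medoid. Provided as an alternative to the shrunken-centroid
#' classifier.
#'
#' @param expr training `expr_matrix`.
#' @param labels training labels.
#' @return List of class `medoid_model` with `medoids` (genes x classes)
#'   and `classes`.
#' @export
fit_medoid_classifier <- function(expr, labels) {
  stopifnot(inherits(expr, "expr_matrix"))
  X <- expr$values
  if (!is.null(names(labels))) labels <- labels[colnames(X)]
  classes <- sort(unique(as.character(labels)))
  med <- sapply(classes, function(k) {
    Xi <- X[, labels == k, drop = FALSE]
    D <- as.matrix(dist(t(Xi)))
    Xi[, which.min(colSums(D))]
  })
  structure(list(medoids = med, classes = classes, unit = expr$unit),
            class = "medoid_model")
}

#' @rdname fit_medoid_classifier
#' @param model a `medoid_model`.
#' @export
predict_medoid <- function(model, expr) {
  stopifnot(inherits(model, "medoid_model"), inherits(expr, "expr_matrix"))
  X <- expr$values[rownames(model$medoids), , drop = FALSE]
  d <- sapply(seq_along(model$classes), function(k)
    colSums((X - model$medoids[, k])^2))
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  setNames(model$classes[apply(d, 1, which.min)], colnames(X))
}
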