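#' Default pipeline configuration
#'
#' Stage toggles and parameters for [run_pipeline()]. Defaults mirror the
#' analysis design: 30-day survival filter, 70:30 stratified split,
#' concordance-index threshold 1, 66% prevalence rule, 137 signature genes,
#' NMF rank grid 2-6 with 30 restarts.
#'
#' @param out_dir output directory.
#' @param seed master seed; stage seeds derive from it.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "preprocess", "subtype", "classify", "network",
#'   "score", "survival")`.
#' @param cohort list of [cohort_config()] overrides for the simulate stage.
#' @param min_days,train_frac,ranks,n_restarts,delta_grid,ci_threshold,
#'   prevalence_min_frac,horizons stage parameters.
#' @param gene_sets optional named list of gene sets for the score stage
#'   (default: the planted signature plus a random control set).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            stages = c("simulate", "preprocess", "subtype",
                                       "classify", "network", "score", "survival"),
                            cohort = list(),
                            min_days = 30, train_frac = 0.7,
                            ranks = 2:6, n_restarts = 30,
                            delta_grid = seq(0, 3, by = 0.5),
                            ci_threshold = 1, prevalence_min_frac = 0.66,
                            horizons = c(365, 1095, 1825),
                            gene_sets = NULL) {
  all_stages <- c("simulate", "preprocess", "subtype", "classify", "network",
                  "score", "survival")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 cohort = cohort, min_days = min_days, train_frac = train_frac,
                 ranks = ranks, n_restarts = n_restarts, delta_grid = delta_grid,
                 ci_threshold = ci_threshold,
                 prevalence_min_frac = prevalence_min_frac,
                 horizons = horizons, gene_sets = gene_sets),
            class = "pipeline_config")
}

#' Run the subtyping pipeline end to end
#'
#' Executes the enabled stages in order on a generated cohort:
#' simulate -> preprocess (30-day filter) -> subtype (consensus NMF) ->
#' classify (stratified split + shrunken centroids + AUC) -> network
#' (per-subtype concordance networks + hubs) -> score (signature ssGSEA +
#' group comparison) -> survival (KM/log-rank, Cox, nomogram, IPCW AUC).
#' Every stage writes its artifacts under `out_dir` and the run closes with
#' a `manifest.json` recording parameters, per-stage outputs and md5
#' hashes. A stage failure aborts with the stage name; artifacts of
#' completed stages are retained.
#'
#' @param config a [pipeline_config()].
#' @return The manifest list, invisibly; also written as JSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list())
  state <- new.env(parent = emptyenv())
  t_total <- Sys.time()

  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    message("[", name, "] running ...")
    t0 <- Sys.time()
    files <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    manifest$stages[[name]] <<- list(
      files = as.list(files),
      md5 = as.list(unname(tools::md5sum(files))),
      seconds = round(elapsed, 2))
    message("[", name, "] done in ", round(elapsed, 1), "s")
  }
  p <- function(f) file.path(config$out_dir, f)

  run_stage("simulate", function() {
    cfg <- do.call(cohort_config, c(config$cohort,
                                    if (is.null(config$cohort$seed)) list(seed = config$seed)))
    state$cohort <- generate_cohort(cfg)
    dir <- p("cohort")
    write_cohort(state$cohort, dir)
    list.files(dir, full.names = TRUE)
  })

  run_stage("preprocess", function() {
    ch <- state$cohort
    clin <- filter_short_survivors(ch$clinical, config$min_days)
    expr <- subset_expr(ch$expression, samples = clin$sample_id)
    state$clinical <- clin
    state$expr <- log2_tpm(expr)
    write.table(clin, p("clinical_filtered.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    p("clinical_filtered.tsv")
  })

  run_stage("subtype", function() {
    st <- nmf_subtype(state$expr, state$cohort$signature_genes,
                      ranks = config$ranks, n_restarts = config$n_restarts,
                      seed = config$seed)
    state$subtyping <- st
    lab_df <- data.frame(sample_id = names(st$labels), subtype = unname(st$labels))
    write.table(lab_df, p("subtype_labels.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(list(selected_rank = st$selected_rank,
                              cophenetic = as.list(st$cophenetic_by_rank),
                              dispersion = as.list(st$dispersion_by_rank)),
                         p("rank_metrics.json"), auto_unbox = TRUE, digits = NA)
    c(p("subtype_labels.tsv"), p("rank_metrics.json"))
  })

  run_stage("classify", function() {
    labels <- state$subtyping$labels
    sig_expr <- subset_expr(state$expr,
                            genes = intersect(state$cohort$signature_genes,
                                              gene_ids(state$expr)))
    sp <- stratified_split(names(labels), labels, config$train_frac,
                           seed = config$seed)
    model <- fit_centroid_classifier(subset_expr(sig_expr, samples = sp$train),
                                     labels[sp$train],
                                     delta_grid = config$delta_grid,
                                     seed = config$seed)
    pred <- predict_subtype(model, subset_expr(sig_expr, samples = sp$test))
    pos <- if ("C1" %in% colnames(pred$scores)) "C1" else colnames(pred$scores)[1]
    auc <- roc_auc(pred$scores[, pos], labels[sp$test] == pos)
    state$classifier <- list(model = model, split = sp, pred = pred, auc = auc)
    out <- data.frame(sample_id = sp$test, predicted = unname(pred$label),
                      c1_score = unname(pred$scores[, pos]))
    write.table(out, p("classifier_predictions.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(list(test_auc = auc, delta = model$delta,
                              n_train = length(sp$train), n_test = length(sp$test)),
                         p("classifier_metrics.json"), auto_unbox = TRUE, digits = NA)
    c(p("classifier_predictions.tsv"), p("classifier_metrics.json"))
  })

  run_stage("network", function() {
    labels <- state$subtyping$labels
    ch <- state$cohort
    files <- character(0)
    for (cl in c("C1", "C2")) {
      sub <- names(labels)[labels == cl]
      if (length(sub) < 3) next
      ex <- subset_expr(state$expr, samples = sub)
      net_genes <- unique(c(ch$interaction_catalog$gene_a,
                            ch$interaction_catalog$gene_b))
      disc <- discretize_tertiles(ex, intersect(net_genes, gene_ids(ex)))
      admitted <- prevalence_filter(disc, config$prevalence_min_frac)
      cand <- candidate_edges(ch$interaction_catalog, ch$lr_seed_genes, admitted)
      net <- suppressMessages(build_network(disc, cand,
                                            ci_threshold = config$ci_threshold,
                                            subtype = cl))
      f <- p(paste0("network_", cl, ".tsv"))
      write.table(net$edges, f, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, f)
      state$networks[[cl]] <- net
      if (nrow(net$edges)) {
        hubs <- hub_intersection(net)
        fh <- p(paste0("hubs_", cl, ".txt"))
        writeLines(hubs, fh)
        files <- c(files, fh)
      }
    }
    files
  })

  run_stage("score", function() {
    sets <- config$gene_sets
    if (is.null(sets)) {
      old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
      set.seed(config$seed)
      sets <- list(
        signature = state$cohort$signature_genes,
        random_control = sample(gene_ids(state$expr),
                                length(state$cohort$signature_genes)))
    }
    sc <- score_collection(state$expr, sets)
    cmp <- compare_group_scores(sc, state$subtyping$labels[colnames(sc)],
                                adjust = TRUE)
    state$scores <- sc
    write.table(data.frame(set = rownames(sc), sc, check.names = FALSE),
                p("set_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cmp, p("set_score_tests.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    c(p("set_scores.tsv"), p("set_score_tests.tsv"))
  })

  run_stage("survival", function() {
    clin <- state$clinical
    labels <- state$subtyping$labels[clin$sample_id]
    clin$subtype_nmf <- unname(labels)
    km <- km_logrank(clin, labels)
    fit <- cox_fit(clin, c("subtype_nmf", "age", "grade"))
    horizons <- config$horizons[config$horizons <= max(clin$os_time)]
    res <- list(logrank_p = km$logrank_p, cox = fit$table)
    if (length(horizons) >= 1 && nrow(fit$table) >= 2) {
      nom <- build_nomogram(fit, clin, horizons)
      pred <- predict_nomogram(nom, clin)
      aucs <- vapply(seq_along(horizons), function(i)
        tryCatch(time_dependent_auc(pred$lp, clin, horizons[i]),
                 error = function(e) NA_real_), 0.0)
      res$nomogram_auc <- setNames(as.list(aucs), paste0("t", horizons))
      state$nomogram <- nom
    }
    jsonlite::write_json(res, p("survival_metrics.json"), auto_unbox = TRUE,
                         digits = NA)
    p("survival_metrics.json")
  })

  manifest$elapsed_seconds <- round(as.numeric(difftime(Sys.time(), t_total,
                                                        units = "secs")), 2)
  manifest$parameters <- unclass(config)[setdiff(names(unclass(config)), "gene_sets")]
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
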