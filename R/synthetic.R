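#' Configuration for the synthetic glioma cohort generator
#'
#' The generator emulates the statistical structure the subtyping analysis
#' assumes in a bulk expression cohort: two latent subtypes (C1/C2) driving
#' an efferocytosis-like gene program, subtype- and age-dependent hazard,
#' independent right-censoring, and concordantly co-expressed
#' ligand-receptor pairs embedded among uncoupled decoy pairs.
#'
#' @param n_samples number of samples.
#' @param n_genes total number of genes.
#' @param n_signature_genes size of the subtype-driving signature
#'   (default 137, the size of the efferocytosis gene program).
#' @param signature_effect log2-scale mean shift of signature genes in C1.
#' @param frac_c1 proportion of C1 samples, in (0, 1).
#' @param n_lr_pairs number of planted concordant ligand-receptor pairs.
#' @param lr_coupling within-C1 correlation of each planted pair, in [0, 1].
#' @param subtype_hazard_ratio hazard ratio C1 vs C2 (default 5.583).
#' @param age_hazard_ratio_per_year per-year hazard ratio (default 1.070).
#' @param censor_rate target fraction of censored samples, in [0, 1).
#' @param noise_sd log2-scale residual SD.
#' @param seed integer RNG seed.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 200, n_genes = 500, n_signature_genes = 137,
                          signature_effect = 1.0, frac_c1 = 0.5,
                          n_lr_pairs = 10, lr_coupling = 0.9,
                          subtype_hazard_ratio = 5.583,
                          age_hazard_ratio_per_year = 1.070,
                          censor_rate = 0.3, noise_sd = 1.0, seed = 1) {
  cfg <- list(n_samples = n_samples, n_genes = n_genes,
              n_signature_genes = n_signature_genes,
              signature_effect = signature_effect, frac_c1 = frac_c1,
              n_lr_pairs = n_lr_pairs, lr_coupling = lr_coupling,
              subtype_hazard_ratio = subtype_hazard_ratio,
              age_hazard_ratio_per_year = age_hazard_ratio_per_year,
              censor_rate = censor_rate, noise_sd = noise_sd,
              seed = as.integer(seed))
  .check_count <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v != round(v))
      stop("invalid `", field, "`: must be a positive integer count")
  }
  for (f in c("n_samples", "n_genes", "n_signature_genes", "n_lr_pairs"))
    .check_count(f)
  if (cfg$n_signature_genes > cfg$n_genes)
    stop("invalid `n_signature_genes`: exceeds `n_genes`")
  if (cfg$n_genes < cfg$n_signature_genes + 2 * cfg$n_lr_pairs + 1)
    stop("invalid `n_genes`: too small for signature plus ligand-receptor pairs")
  if (!(cfg$frac_c1 > 0 && cfg$frac_c1 < 1))
    stop("invalid `frac_c1`: must be in (0, 1)")
  if (cfg$lr_coupling < 0 || cfg$lr_coupling > 1)
    stop("invalid `lr_coupling`: must be in [0, 1]")
  if (cfg$subtype_hazard_ratio <= 0)
    stop("invalid `subtype_hazard_ratio`: must be > 0")
  if (cfg$age_hazard_ratio_per_year <= 0)
    stop("invalid `age_hazard_ratio_per_year`: must be > 0")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    stop("invalid `censor_rate`: must be in [0, 1)")
  if (cfg$noise_sd <= 0) stop("invalid `noise_sd`: must be > 0")
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate a synthetic cohort
#'
#' Draws a fully reproducible cohort under `config`: log-normal expression
#' with per-gene baseline log2 means drawn from N(3, 1) and residual log2
#' SD `noise_sd`; a two-sided signature program in which 70% of signature
#' genes are shifted up by `signature_effect` in C1 and the remaining 30%
#' up in C2 (so C1 has the higher mean signature expression, and the two
#' subtype archetypes are distinct expression patterns rather than a pure
#' rescaling of one another, as in real subtype programs); each planted
#' ligand-receptor pair sharing a
#' latent factor with correlation `lr_coupling` within C1 samples,
#' exponential survival with log-hazard
#' `log(subtype_hazard_ratio) * 1[C1] + log(age_hazard_ratio_per_year) * (age - mean(age))`,
#' and independent exponential censoring calibrated to the target censoring
#' fraction. Decoy (uncoupled) interaction pairs are included at three times
#' the number of planted pairs, each anchored at a ligand/receptor seed
#' gene, so network precision and recall are meaningful downstream.
#'
#' @param config a [cohort_config()].
#' @return A `synthetic_cohort` list: `expression` (`expr_matrix`, TPM-like),
#'   `clinical` (data.frame: sample_id, os_time, os_event, age, grade),
#'   `truth_labels` (named "C1"/"C2" vector), `signature_genes`,
#'   `lr_seed_genes`, `interaction_catalog` (gene_a, gene_b, source),
#'   `planted_edges`, and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  n <- config$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  n_c1 <- max(1L, min(n - 1L, round(config$frac_c1 * n)))
  truth <- setNames(rep("C2", n), samples)
  truth[sample(samples, n_c1)] <- "C1"
  is_c1 <- truth == "C1"

  np <- config$n_lr_pairs
  sig_genes <- sprintf("SIG%03d", seq_len(config$n_signature_genes))
  lig <- sprintf("LIG%03d", seq_len(np))
  rec <- sprintf("REC%03d", seq_len(np))
  n_bg <- config$n_genes - config$n_signature_genes - 2L * np
  bg <- sprintf("BG%04d", seq_len(n_bg))
  genes <- c(sig_genes, lig, rec, bg)

  # log2-scale expression: per-gene baselines plus residual noise
  baseline <- rnorm(length(genes), mean = 3, sd = 1)
  L <- baseline + matrix(rnorm(length(genes) * n, mean = 0, sd = config$noise_sd),
                         nrow = length(genes), dimnames = list(genes, samples))
  # two-sided signature program: 70% of signature genes up in C1, 30% in C2
  n_up <- round(0.7 * length(sig_genes))
  c1_program <- sig_genes[seq_len(n_up)]
  c2_program <- setdiff(sig_genes, c1_program)
  L[c1_program, is_c1] <- L[c1_program, is_c1] + config$signature_effect
  L[c2_program, !is_c1] <- L[c2_program, !is_c1] + config$signature_effect
  # couple each ligand-receptor pair through a shared factor within C1
  rho <- config$lr_coupling
  for (p in seq_len(np)) {
    z <- rnorm(sum(is_c1))
    for (g in c(lig[p], rec[p])) {
      e <- rnorm(sum(is_c1))
      L[g, is_c1] <- baseline[match(g, genes)] +
        config$noise_sd * (sqrt(rho) * z + sqrt(1 - rho) * e)
    }
  }
  expression <- expr_matrix(2^L, "tpm")

  # interaction catalog: planted pairs + 3x decoys anchored at seed genes
  seed_genes <- c(lig, rec)
  planted <- data.frame(gene_a = lig, gene_b = rec, source = "planted",
                        stringsAsFactors = FALSE)
  n_decoy <- 3L * np
  decoy_a <- sample(seed_genes, n_decoy, replace = TRUE)
  decoy_b <- sample(bg, n_decoy, replace = n_decoy > n_bg)
  decoys <- data.frame(gene_a = decoy_a, gene_b = decoy_b, source = "decoy",
                       stringsAsFactors = FALSE)
  catalog <- rbind(planted, decoys)
  key <- apply(catalog[, 1:2], 1, function(r) paste(sort(r), collapse = "|"))
  catalog <- catalog[!duplicated(key), , drop = FALSE]
  rownames(catalog) <- NULL

  # clinical covariates and survival
  age <- runif(n, 20, 80)
  grade <- integer(n)
  grade[is_c1] <- sample(2:4, sum(is_c1), replace = TRUE, prob = c(0.15, 0.35, 0.50))
  grade[!is_c1] <- sample(2:4, sum(!is_c1), replace = TRUE, prob = c(0.45, 0.35, 0.20))
  lp <- log(config$subtype_hazard_ratio) * as.numeric(is_c1) +
    log(config$age_hazard_ratio_per_year) * (age - mean(age))
  lambda0 <- log(2) / 900  # baseline median survival of 900 days
  t_event <- rexp(n, rate = lambda0 * exp(lp))
  if (config$censor_rate > 0) {
    # exponential censoring rate solved so the expected censored fraction
    # matches the target, given the drawn event times
    f <- function(th) mean(1 - exp(-th * t_event)) - config$censor_rate
    theta <- uniroot(f, lower = 1e-10, upper = 1, extendInt = "upX")$root
    t_cens <- rexp(n, rate = theta)
  } else {
    t_cens <- rep(Inf, n)
  }
  os_time <- pmax(round(pmin(t_event, t_cens), 1), 0.1)
  os_event <- as.integer(t_event <= t_cens)

  clinical <- data.frame(sample_id = samples, os_time = os_time,
                         os_event = os_event, age = age, grade = grade,
                         subtype = unname(truth), stringsAsFactors = FALSE)

  structure(list(expression = expression, clinical = clinical,
                 truth_labels = truth, signature_genes = sig_genes,
                 c1_program_genes = c1_program,
                 lr_seed_genes = seed_genes,
                 interaction_catalog = catalog,
                 planted_edges = catalog[catalog$source == "planted", , drop = FALSE],
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d genes x %d samples; %d C1 / %d C2; %d planted + %d decoy pairs\n",
              nrow(x$expression$values), ncol(x$expression$values),
              sum(x$truth_labels == "C1"), sum(x$truth_labels == "C2"),
              nrow(x$planted_edges),
              sum(x$interaction_catalog$source == "decoy")))
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' Writes `expression.tsv`, `clinical.tsv`, `catalog.tsv`, `truth.tsv`,
#' `signature.txt`, `lr_seeds.txt`, and a `manifest.json` recording the
#' generating configuration (including the seed) and the file list, so the
#' cohort can be regenerated or re-read exactly.
#'
#' @param cohort a `synthetic_cohort`.
#' @param directory output directory (created if absent).
#' @return Character vector of written file paths, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop("cannot create directory: ", directory)
  p <- function(f) file.path(directory, f)
  v <- cohort$expression$values
  df <- data.frame(gene_id = rownames(v),
                   apply(v, 2, function(col) sprintf("%.17g", col)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  tryCatch({
    write.table(df, p("expression.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cohort$clinical, p("clinical.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cohort$interaction_catalog, p("catalog.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(sample_id = names(cohort$truth_labels),
                           subtype = unname(cohort$truth_labels)),
                p("truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(cohort$signature_genes, p("signature.txt"))
    writeLines(cohort$lr_seed_genes, p("lr_seeds.txt"))
    files <- c("expression.tsv", "clinical.tsv", "catalog.tsv", "truth.tsv",
               "signature.txt", "lr_seeds.txt")
    manifest <- list(config = unclass(cohort$config),
                     unit = cohort$expression$unit, files = files)
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }, error = function(e) stop("failed writing cohort under '", directory, "': ",
                              conditionMessage(e)))
  invisible(p(c("expression.tsv", "clinical.tsv", "catalog.tsv", "truth.tsv",
                "signature.txt", "lr_seeds.txt", "manifest.json")))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory directory containing the cohort files.
#' @return A list with `expression`, `clinical`, `interaction_catalog`,
#'   `truth_labels`, `signature_genes`, `lr_seed_genes`, and `manifest`.
#' @export
read_cohort <- function(directory) {
  p <- function(f) file.path(directory, f)
  manifest <- jsonlite::read_json(p("manifest.json"), simplifyVector = TRUE)
  truth_df <- read.delim(p("truth.tsv"), stringsAsFactors = FALSE)
  list(expression = read_expression(p("expression.tsv"), unit = manifest$unit),
       clinical = read_clinical(p("clinical.tsv")),
       interaction_catalog = read.delim(p("catalog.tsv"), stringsAsFactors = FALSE),
       truth_labels = setNames(truth_df$subtype, truth_df$sample_id),
       signature_genes = read_gene_list(p("signature.txt")),
       lr_seed_genes = read_gene_list(p("lr_seeds.txt")),
       manifest = manifest)
}
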