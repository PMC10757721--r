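#' Read a gene-by-sample expression table
#'
#' Reads a TSV/CSV file whose first column holds gene symbols and remaining
#' columns one sample each. Duplicate gene symbols are collapsed by taking
#' the per-sample maximum (the usual probe-collapse policy), with a warning.
#'
#' @param path file path; delimiter inferred from the extension
#'   (`.csv` means comma, anything else tab).
#' @param unit unit tag of the stored values, see [expr_matrix()].
#' @return An `expr_matrix`.
#' @export
read_expression <- function(path, unit = c("counts", "tpm", "log2tpm")) {
  unit <- match.arg(unit)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression table needs a gene column plus >= 1 sample column: ", path)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at gene '%s', column '%s' in %s",
                 genes[bad[1]], colnames(m)[bad[2]], path))
  }
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning(length(dup), " duplicated gene symbol(s) collapsed by max: ",
            paste(head(dup, 5), collapse = ", "))
    m <- do.call(rbind, lapply(split(seq_along(genes), genes), function(i) {
      apply(m[i, , drop = FALSE], 2, max)
    }))
    # split() sorts; restore first-appearance order
    m <- m[unique(genes), , drop = FALSE]
  } else {
    rownames(m) <- genes
  }
  expr_matrix(m, unit)
}

#' Write an expression matrix as TSV
#'
#' @param x an `expr_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample clinical table
#'
#' Expects a TSV with at least `sample_id`, `os_time` (days) and `os_event`
#' (0/1); any further columns are kept as covariates.
#'
#' @param path file path.
#' @return A `data.frame` with one row per sample.
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "os_time", "os_event")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("clinical table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in clinical table: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!all(df$os_event %in% c(0, 1))) stop("os_event must be 0/1")
  if (any(df$os_time <= 0)) stop("os_time must be positive")
  df
}

#' Read a plain-text gene list (one symbol per line)
#'
#' @param path file path; blank lines and lines starting with `#` ignored.
#' @return Character vector of unique symbols, input order preserved.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (!length(x)) stop("empty gene list: ", path)
  unique(x)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT layout: one set per line, tab-separated
#' `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path file path.
#' @return Named list of character vectors (unique members per set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line (need name, description, members): ",
                            substr(l, 1, 60))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Convert raw counts to transcripts per million
#'
#' Per sample: `rate_g = count_g / length_g`, then
#' `tpm_g = rate_g / sum(rate) * 1e6`, so every sample column sums to one
#' million.
#'
#' @param expr an `expr_matrix` with unit `"counts"`.
#' @param gene_lengths named numeric vector of transcript lengths in bp,
#'   covering every gene in `expr`.
#' @return An `expr_matrix` with unit `"tpm"`.
#' @export
counts_to_tpm <- function(expr, gene_lengths) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$unit != "counts") stop("counts_to_tpm() expects unit 'counts'; got '", expr$unit, "'")
  missing <- setdiff(rownames(expr$values), names(gene_lengths))
  if (length(missing))
    stop("gene length missing for: ", paste(head(missing, 10), collapse = ", "))
  len <- gene_lengths[rownames(expr$values)]
  if (any(len <= 0)) stop("gene lengths must be > 0")
  rate <- expr$values / len
  tot <- colSums(rate)
  if (any(tot == 0))
    stop("sample(s) with zero total rate: ",
         paste(colnames(expr$values)[tot == 0], collapse = ", "))
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  expr_matrix(tpm, "tpm")
}

#' Drop patients with very short follow-up
#'
#' Removes samples whose overall survival is strictly below `min_days`
#' (the standard exclusion of early deaths that mostly reflect perioperative
#' mortality); samples at exactly `min_days` are retained.
#'
#' @param clinical clinical `data.frame` with an `os_time` column (days).
#' @param min_days lower bound, default 30.
#' @return The filtered clinical table.
#' @export
filter_short_survivors <- function(clinical, min_days = 30) {
  stopifnot("os_time" %in% names(clinical))
  keep <- clinical$os_time >= min_days
  removed <- sum(!keep)
  if (removed > 0)
    message(removed, " sample(s) removed with os_time < ", min_days, " days")
  out <- clinical[keep, , drop = FALSE]
  if (!nrow(out)) stop("no samples left after the ", min_days, "-day filter")
  rownames(out) <- NULL
  out
}

#' Stratified train/test split
#'
#' Splits sample ids into train and test sets preserving per-label
#' proportions to within one sample, reproducibly from `seed`.
#'
#' @param ids character vector of sample ids.
#' @param labels class label per sample (same length as `ids`).
#' @param train_frac fraction assigned to the training set, in (0, 1).
#' @param seed integer RNG seed.
#' @return List with `train` and `test` character vectors (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(ids, labels, train_frac = 0.7, seed = 1) {
  if (length(ids) != length(labels)) stop("ids and labels differ in length")
  if (!(train_frac > 0 && train_frac < 1)) stop("train_frac must be in (0, 1)")
  tab <- table(labels)
  if (any(tab < 2))
    stop("label(s) with < 2 samples: ", paste(names(tab)[tab < 2], collapse = ", "))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  train <- unlist(lapply(split(ids, labels), function(g) {
    n_tr <- round(train_frac * length(g))
    n_tr <- max(1L, min(length(g) - 1L, n_tr))
    sample(g, n_tr)
  }), use.names = FALSE)
  list(train = ids[ids %in% train], test = ids[!ids %in% train])
}

# Save/restore global RNG state so seeded helpers do not disturb the caller.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
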