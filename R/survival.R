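#' Kaplan-Meier curves and log-rank test between groups
#'
#' @param clinical data.frame with `os_time`, `os_event`.
#' @param group_labels group per sample (same order as `clinical` rows, or
#'   named by `sample_id`).
#' @return List of class `km_result`: `fit` (a [survival::survfit] object),
#'   `logrank_chisq`, `logrank_p`, `groups`.
#' @export
km_logrank <- function(clinical, group_labels) {
  g <- .align_labels(clinical, group_labels)
  if (length(unique(g)) < 2) stop("need >= 2 groups")
  events_per_group <- tapply(clinical$os_event, g, sum)
  if (any(events_per_group == 0))
    warning("group(s) without events: ",
            paste(names(events_per_group)[events_per_group == 0], collapse = ", "))
  df <- data.frame(os_time = clinical$os_time, os_event = clinical$os_event, group = g)
  fit <- survival::survfit(survival::Surv(os_time, os_event) ~ group, data = df)
  sd <- survival::survdiff(survival::Surv(os_time, os_event) ~ group, data = df)
  p <- pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
  structure(list(fit = fit, logrank_chisq = unname(sd$chisq), logrank_p = p,
                 groups = sort(unique(g))),
            class = "km_result")
}

.align_labels <- function(clinical, labels) {
  if (!is.null(names(labels)) && "sample_id" %in% names(clinical)) {
    missing <- setdiff(clinical$sample_id, names(labels))
    if (length(missing)) stop("labels missing for sample(s): ",
                              paste(head(missing, 5), collapse = ", "))
    labels <- labels[clinical$sample_id]
  }
  if (length(labels) != nrow(clinical)) stop("labels do not match the clinical table")
  as.character(labels)
}

#' Cox proportional-hazards fits (univariate or multivariate)
#'
#' Maximizes the partial likelihood with the Efron tie correction and
#' returns per-term hazard ratios with Wald confidence intervals and
#' p-values. In univariate mode each variable is fitted in its own model.
#'
#' @param clinical data.frame with `os_time`, `os_event`, and the
#'   covariates named in `variables`.
#' @param variables character vector of covariate column names.
#' @param mode `"multivariate"` (one joint model) or `"univariate"`.
#' @return For multivariate: a `survival_fit` list (`model` = the coxph
#'   object, `table` = data.frame term/coef/HR/CI/p, `baseline` = baseline
#'   cumulative hazard at covariate value zero). For univariate: a named
#'   list of such objects, one per variable.
#' @export
cox_fit <- function(clinical, variables, mode = c("multivariate", "univariate")) {
  mode <- match.arg(mode)
  missing <- setdiff(variables, names(clinical))
  if (length(missing)) stop("covariate(s) not in clinical table: ",
                            paste(missing, collapse = ", "))
  for (v in variables)
    if (length(unique(clinical[[v]])) < 2) stop("covariate '", v, "' is constant")
  n_events <- sum(clinical$os_event)
  if (mode == "univariate")
    return(setNames(lapply(variables, function(v)
      cox_fit(clinical, v, mode = "multivariate")), variables))
  if (n_events < 5 * length(variables))
    warning("few events (", n_events, ") for ", length(variables), " parameter(s)")
  fml <- stats::as.formula(paste("survival::Surv(os_time, os_event) ~",
                                 paste(variables, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = clinical, ties = "efron"),
    error = function(e) stop("Cox fit failed: ", conditionMessage(e)),
    warning = function(w) {
      if (grepl("converge|infinite", conditionMessage(w)))
        stop("Cox fit did not converge (possible separation): ", conditionMessage(w))
      suppressWarnings(survival::coxph(fml, data = clinical, ties = "efron"))
    })
  s <- summary(fit)
  tab <- data.frame(term = rownames(s$coefficients),
                    coef = s$coefficients[, "coef"],
                    hr = s$coefficients[, "exp(coef)"],
                    ci_lower = s$conf.int[, "lower .95"],
                    ci_upper = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  baseline <- survival::basehaz(fit, centered = FALSE)
  structure(list(model = fit, table = tab, baseline = baseline,
                 variables = variables),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat("<survival_fit> Cox proportional hazards (Efron ties)\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Build a points-based nomogram from a multivariate Cox fit
#'
#' Each covariate's contribution `coef * x` is shifted so its minimum over
#' the observed range is 0 and rescaled so the widest-ranging covariate
#' spans 0-100 points. Total points map linearly back to the Cox linear
#' predictor, and survival probabilities at the requested horizons come
#' from the baseline cumulative hazard: `S(t|x) = exp(-Lambda0(t) * exp(lp))`.
#'
#' @param fit a multivariate `survival_fit` with >= 2 terms.
#' @param clinical the data the model was fitted on (defines covariate
#'   ranges).
#' @param horizons evaluation times in days (default 1/3/5 years).
#' @return List of class `nomogram_model`: `fit`, `scales` (per-term
#'   data.frame: term, coef, min, points_per_unit), `points_per_lp`,
#'   `lp_offset`, `horizons`, `baseline_surv` (survival at each horizon for
#'   lp = 0).
#' @export
build_nomogram <- function(fit, clinical, horizons = c(365, 1095, 1825)) {
  stopifnot(inherits(fit, "survival_fit"))
  if (nrow(fit$table) < 2) stop("nomogram needs a multivariate fit with >= 2 terms")
  max_t <- max(clinical$os_time)
  if (any(horizons > max_t))
    stop("horizon(s) beyond observed follow-up (", round(max_t), " days): ",
         paste(horizons[horizons > max_t], collapse = ", "))
  mm <- .cox_model_matrix(fit$model, clinical)
  coefs <- stats::coef(fit$model)
  contrib <- sweep(mm, 2, coefs, "*")
  rng <- apply(contrib, 2, range)
  widest <- max(rng[2, ] - rng[1, ])
  if (widest <= 0) stop("all covariate contributions are constant")
  scales <- data.frame(term = colnames(mm), coef = unname(coefs),
                       contrib_min = rng[1, ],
                       points_per_contrib = 100 / widest,
                       stringsAsFactors = FALSE)
  rownames(scales) <- NULL
  lam0 <- .baseline_cumhaz_fun(fit)
  structure(list(fit = fit, scales = scales, widest = widest,
                 horizons = horizons,
                 baseline_surv = exp(-lam0(horizons))),
            class = "nomogram_model")
}

# Design matrix for a coxph model on new data, matched to the coefficient
# names (no intercept, no response needed in `data`).
.cox_model_matrix <- function(model, data) {
  tt <- stats::delete.response(stats::terms(model))
  mm <- stats::model.matrix(tt, data = data)
  mm[, names(stats::coef(model)), drop = FALSE]
}

.baseline_cumhaz_fun <- function(fit) {
  bh <- fit$baseline
  function(t) {
    vapply(t, function(ti) {
      idx <- bh$time <= ti
      if (!any(idx)) 0 else max(bh$hazard[idx])
    }, 0.0)
  }
}

#' Predict survival probabilities from a nomogram
#'
#' Converts covariates to per-variable points, totals them, maps the total
#' back to the Cox linear predictor, and evaluates
#' `S(t|x) = exp(-Lambda0(t) * exp(lp))` at each horizon. Identical, to
#' numerical precision, to predicting directly from the underlying Cox
#' model.
#'
#' @param nomogram a `nomogram_model`.
#' @param newdata data.frame of covariates.
#' @return List: `points` (samples x terms), `total_points`, `lp`,
#'   `surv` (samples x horizons matrix).
#' @export
predict_nomogram <- function(nomogram, newdata) {
  stopifnot(inherits(nomogram, "nomogram_model"))
  fit <- nomogram$fit
  mm <- .cox_model_matrix(fit$model, newdata)
  contrib <- sweep(mm, 2, stats::coef(fit$model), "*")
  pts <- sweep(contrib, 2, nomogram$scales$contrib_min, "-") *
    (100 / nomogram$widest)
  total <- rowSums(pts)
  lp <- total * nomogram$widest / 100 + sum(nomogram$scales$contrib_min)
  lam0 <- .baseline_cumhaz_fun(fit)
  surv <- outer(exp(lp), lam0(nomogram$horizons),
                function(e, l) exp(-l * e))
  colnames(surv) <- paste0("t", nomogram$horizons)
  list(points = pts, total_points = total, lp = lp, surv = surv)
}

#' Time-dependent AUC under right censoring (IPCW)
#'
#' Cumulative/dynamic AUC at horizon `t`: cases are samples with an
#' observed event by `t`, controls are samples still at risk beyond `t`.
#' Case contributions are weighted by the inverse probability of remaining
#' uncensored just before their event time, estimated by the Kaplan-Meier
#' curve of the censoring distribution (Uno-type estimator). Ties in the
#' risk score count 1/2. With no censoring this reduces to the plain ROC
#' AUC of event-by-t status against the score.
#'
#' @param risk_scores numeric risk score per sample (higher = higher risk).
#' @param clinical data.frame with `os_time`, `os_event`.
#' @param horizon_t evaluation time.
#' @return AUC estimate in [0, 1].
#' @export
time_dependent_auc <- function(risk_scores, clinical, horizon_t) {
  time <- clinical$os_time; event <- clinical$os_event
  if (length(risk_scores) != length(time)) stop("risk_scores do not match clinical")
  cases <- which(time <= horizon_t & event == 1)
  controls <- which(time > horizon_t)
  if (!length(cases)) stop("no events before the horizon")
  if (!length(controls)) stop("no samples at risk beyond the horizon")
  # KM of the censoring distribution
  cfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- function(t) {
    vapply(t, function(ti) {
      idx <- cfit$time < ti
      if (!any(idx)) 1 else min(cfit$surv[idx])
    }, 0.0)
  }
  w <- 1 / pmax(G(time[cases]), 1e-10)
  num <- 0; den <- 0
  for (i in seq_along(cases)) {
    mi <- risk_scores[cases[i]]
    conc <- sum(mi > risk_scores[controls]) + 0.5 * sum(mi == risk_scores[controls])
    num <- num + w[i] * conc
    den <- den + w[i] * length(controls)
  }
  num / den
}

#' Calibration of nomogram-predicted survival
#'
#' Bins samples by predicted survival probability at `horizon_t` (quantile
#' bins) and compares the mean prediction per bin with the Kaplan-Meier
#' estimate at `horizon_t` within the bin. Degenerate bins (identical
#' predictions straddling a boundary) are merged with a message.
#'
#' @param nomogram a `nomogram_model` whose horizons include `horizon_t`.
#' @param clinical data.frame with `os_time`, `os_event` and the model
#'   covariates.
#' @param horizon_t evaluation time (must be one of the nomogram horizons).
#' @param n_bins number of quantile bins (default 4).
#' @return data.frame: bin, n, predicted (mean), observed (KM), ci_lower,
#'   ci_upper.
#' @export
calibration_curve <- function(nomogram, clinical, horizon_t, n_bins = 4) {
  stopifnot(inherits(nomogram, "nomogram_model"))
  hcol <- match(horizon_t, nomogram$horizons)
  if (is.na(hcol)) stop("horizon_t must be one of the nomogram horizons")
  if (nrow(clinical) < n_bins * 20)
    warning("fewer than ", n_bins * 20, " samples; calibration bins will be noisy")
  pred <- predict_nomogram(nomogram, clinical)$surv[, hcol]
  br <- unique(quantile(pred, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) - 1 < n_bins)
    message("degenerate bin boundaries merged; using ", length(br) - 1, " bins")
  bins <- cut(pred, breaks = br, include.lowest = TRUE)
  out <- lapply(levels(bins), function(b) {
    idx <- bins == b
    kf <- survival::survfit(survival::Surv(os_time, os_event) ~ 1,
                            data = clinical[idx, , drop = FALSE])
    sm <- summary(kf, times = horizon_t, extend = TRUE)
    data.frame(bin = b, n = sum(idx), predicted = mean(pred[idx]),
               observed = sm$surv, ci_lower = sm$lower, ci_upper = sm$upper,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$predicted), ]
}

#' Point-biserial correlation
#'
#' Pearson correlation between a 0/1-coded binary variable and a continuous
#' score, with the usual two-sided t-based p-value.
#'
#' @param binary_labels logical or 0/1 vector (both values present).
#' @param continuous_scores numeric vector.
#' @return List: `r`, `p`.
#' @export
point_biserial <- function(binary_labels, continuous_scores) {
  y <- as.numeric(as.logical(binary_labels))
  if (length(unique(y)) < 2) stop("both label values must be present")
  if (sd(continuous_scores) == 0) stop("scores are constant; correlation undefined")
  t <- cor.test(y, continuous_scores, method = "pearson")
  list(r = unname(t$estimate), p = t$p.value)
}

#' Classify predicted immunotherapy response from TIDE scores
#'
#' Scores above 0 are predicted non-responders, below 0 responders; a score
#' of exactly 0 (not covered by the strict inequalities of the original
#' rule) is treated as non-responder with a warning. Missing scores are
#' excluded with a message listing the samples.
#'
#' @param tide_scores named numeric vector of TIDE scores.
#' @return Named factor with levels `responder`, `non_responder`.
#' @export
classify_icb_response <- function(tide_scores) {
  if (anyNA(tide_scores)) {
    bad <- names(tide_scores)[is.na(tide_scores)]
    message("excluding ", length(bad), " sample(s) with missing TIDE score: ",
            paste(head(bad, 5), collapse = ", "))
    tide_scores <- tide_scores[!is.na(tide_scores)]
  }
  if (any(tide_scores == 0))
    warning(sum(tide_scores == 0),
            " score(s) exactly 0 classified as non-responder")
  out <- factor(ifelse(tide_scores < 0, "responder", "non_responder"),
                levels = c("responder", "non_responder"))
  names(out) <- names(tide_scores)
  out
}

#' Compare responder proportions between groups
#'
#' Chi-square test of the responder/non-responder split across groups.
#'
#' @param response factor from [classify_icb_response()].
#' @param groups group label per sample.
#' @return List: `table`, `chisq`, `p`.
#' @export
compare_response_rates <- function(response, groups) {
  tab <- table(groups, response)
  t <- suppressWarnings(chisq.test(tab))
  list(table = tab, chisq = unname(t$statistic), p = t$p.value)
}
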