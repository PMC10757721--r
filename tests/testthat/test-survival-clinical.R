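fit_cohort <- function(seed = 21, n = 600) {
  ch <- generate_cohort(cohort_config(n_samples = n, seed = seed))
  cl <- ch$clinical
  cl$is_c1 <- as.integer(cl$subtype == "C1")
  cl
}

test_that("KM/log-rank separates the planted subtypes and handles null groups", {
  cl <- fit_cohort()
  km <- km_logrank(cl, setNames(cl$subtype, cl$sample_id))
  expect_lt(km$logrank_p, 0.001)
  # identical groups: no signal
  set.seed(2)
  null_cl <- data.frame(sample_id = sprintf("s%d", 1:200),
                        os_time = rexp(200, 1 / 500), os_event = 1)
  grp <- rep(c("a", "b"), 100)
  km0 <- km_logrank(null_cl, grp)
  expect_gt(km0$logrank_p, 0.05)
  # single-group product-limit estimate is the empirical survival fraction
  one <- data.frame(sample_id = letters[1:4], os_time = c(1, 2, 3, 4), os_event = 1)
  sf <- survival::survfit(survival::Surv(os_time, os_event) ~ 1, data = one)
  expect_equal(sf$surv, c(0.75, 0.5, 0.25, 0))
  expect_error(km_logrank(one, rep("a", 4)), ">= 2 groups")
})

test_that("Cox fits recover planted hazard ratios and flag bad inputs", {
  cl <- fit_cohort()
  uni <- cox_fit(cl, c("is_c1", "age"), mode = "univariate")
  expect_named(uni, c("is_c1", "age"))
  multi <- cox_fit(cl, c("is_c1", "age"))
  hr <- setNames(multi$table$hr, multi$table$term)
  expect_lt(abs(log(hr[["is_c1"]]) - log(5.583)), 0.2 * log(5.583))
  expect_lt(abs(hr[["age"]] - 1.070), 0.015)
  ci <- multi$table[multi$table$term == "is_c1", ]
  expect_true(ci$ci_lower < ci$hr && ci$hr < ci$ci_upper)
  # a covariate independent of survival has HR ~ 1
  set.seed(5)
  cl$noise <- rnorm(nrow(cl))
  f0 <- cox_fit(cl, "noise")
  expect_lt(abs(f0$table$coef), 2 * sqrt(diag(f0$model$var))[1] + 0.05)
  expect_error(cox_fit(cl, "missing_col"), "not in clinical")
  cl$const <- 1
  expect_error(cox_fit(cl, "const"), "constant")
})

test_that("nomogram predictions are a bijection of the Cox linear predictor", {
  cl <- fit_cohort(seed = 33, n = 400)
  fit <- cox_fit(cl, c("is_c1", "age", "grade"))
  nom <- build_nomogram(fit, cl, horizons = c(365, 1095))
  pred <- predict_nomogram(nom, cl)
  # direct Cox prediction: S(t|x) = exp(-Lambda0(t) * exp(lp))
  mm <- cbind(cl$is_c1, cl$age, cl$grade)
  lp <- drop(mm %*% stats::coef(fit$model))
  expect_equal(pred$lp, lp, tolerance = 1e-10, ignore_attr = TRUE)
  bh <- fit$baseline
  for (i in seq_along(nom$horizons)) {
    L0 <- max(c(0, bh$hazard[bh$time <= nom$horizons[i]]))
    expect_equal(unname(pred$surv[, i]), exp(-L0 * exp(lp)), tolerance = 1e-6)
  }
  # reference covariates (all zero) give the baseline survival
  ref <- data.frame(is_c1 = 0, age = 0, grade = 0)
  pref <- predict_nomogram(nom, ref)
  expect_equal(unname(pref$surv[1, ]), unname(nom$baseline_surv), tolerance = 1e-10)
  # raising a positive-coefficient covariate never raises survival
  co <- stats::coef(fit$model)
  v <- names(which(co > 0))[1]
  d1 <- cl[1, ]; d2 <- d1; d2[[sub("^.*\\$", "", v)]] <- d2[[v]] + 10
  expect_true(all(predict_nomogram(nom, d2)$surv <= predict_nomogram(nom, d1)$surv))
  expect_error(build_nomogram(fit, cl, horizons = 10 * max(cl$os_time)),
               "beyond observed follow-up")
})

test_that("IPCW time-dependent AUC behaves like an ROC area", {
  # perfect marker, no censoring
  set.seed(7)
  n <- 120
  t <- sort(rexp(n, 1 / 400))
  cl <- data.frame(sample_id = sprintf("s%d", 1:n), os_time = t, os_event = 1)
  risk <- -t  # larger risk = earlier death, perfect ordering
  expect_equal(time_dependent_auc(risk, cl, 400), 1.0)
  # no censoring: reduces to the plain ROC AUC of event-by-t vs score
  risk2 <- rnorm(n)
  for (h in c(200, 400)) {
    plain <- roc_auc(risk2, cl$os_time <= h)
    expect_equal(time_dependent_auc(risk2, cl, h), plain, tolerance = 1e-12)
  }
  # pure-noise marker under censoring stays near 1/2 (averaged over seeds)
  aucs <- vapply(1:8, function(s) {
    ch <- generate_cohort(cohort_config(n_samples = 250, n_genes = 60,
                                        n_signature_genes = 10, seed = 100 + s))
    set.seed(s)
    time_dependent_auc(rnorm(250), ch$clinical, 365)
  }, 0.0)
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
  expect_error(time_dependent_auc(risk, cl, 1e9), "at risk beyond")
})

test_that("calibration bins agree with the model under self-simulation", {
  cl <- fit_cohort(seed = 55, n = 1000)
  fit <- cox_fit(cl, c("is_c1", "age"))
  nom <- build_nomogram(fit, cl, horizons = 365)
  cal <- calibration_curve(nom, cl, 365, n_bins = 4)
  expect_equal(nrow(cal), 4)
  expect_true(all(diff(cal$predicted) > 0))  # ordered by prediction
  expect_lt(max(abs(cal$predicted - cal$observed)), 0.06)
  # single bin recovers the overall KM estimate at the horizon
  cal1 <- calibration_curve(nom, cl, 365, n_bins = 1)
  sf <- summary(survival::survfit(survival::Surv(os_time, os_event) ~ 1, data = cl),
                times = 365)
  expect_equal(cal1$observed, sf$surv)
})

test_that("point-biserial correlation is Pearson on 0/1 coding", {
  set.seed(10)
  y <- rep(c(0, 1), 5)
  x <- rnorm(10) + y
  r <- point_biserial(y, x)
  ct <- cor.test(as.numeric(y), x)
  expect_equal(r$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(r$p, ct$p.value, tolerance = 1e-12)
  # equal group means: r = 0
  x0 <- c(1, 2, 3, 1, 2, 3)
  expect_equal(point_biserial(c(0, 0, 0, 1, 1, 1), x0)$r, 0, tolerance = 1e-12)
  # antisymmetry under label inversion
  expect_equal(point_biserial(1 - y, x)$r, -r$r, tolerance = 1e-12)
  expect_error(point_biserial(y, rep(2, 10)), "constant")
  expect_error(point_biserial(rep(1, 10), x), "both label values")
})

test_that("ICB response classification follows the TIDE sign rule", {
  sc <- c(a = 0.5, b = -0.3, d = 1.2)
  r <- classify_icb_response(sc)
  expect_equal(as.character(r[c("a", "b", "d")]),
               c("non_responder", "responder", "non_responder"))
  expect_warning(r0 <- classify_icb_response(c(x = 0)), "exactly 0")
  expect_equal(as.character(r0), "non_responder")
  expect_message(rna <- classify_icb_response(c(a = NA, b = -1)), "missing")
  expect_length(rna, 1)
  # responder proportions compared by chi-square
  set.seed(1)
  resp <- classify_icb_response(setNames(rnorm(80), sprintf("s%d", 1:80)))
  cmp <- compare_response_rates(resp, rep(c("C1", "C2"), 40))
  expect_true(cmp$p > 0 && cmp$p <= 1)
  expect_equal(sum(cmp$table), 80)
})
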