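# efferotype

Efferocytosis-related transcriptomic subtyping of glioma.

Efferocytosis — the phagocytic clearance of apoptotic cells, triggered by
"find me"/"eat me" ligand–receptor signalling — shapes the glioma immune
microenvironment. `efferotype` implements a complete analysis chain for
testing whether an efferocytosis gene signature stratifies tumours into a
signature-high subtype (**C1**, worse survival) and a signature-low subtype
(**C2**):

- **Subtype discovery** — consensus non-negative matrix factorization
  (generalized KL divergence, C++ multiplicative updates) on the signature
  genes, with cophenetic/dispersion rank selection
  (`nmf_subtype()`, `consensus_over_restarts()`, `select_rank()`).
- **Subtype transfer** — a nearest-shrunken-centroid classifier with
  cross-validated shrinkage (`fit_centroid_classifier()`,
  `predict_subtype()`), plus a k-medoids variant.
- **Ligand–receptor concordance networks** — tertile discretization,
  prevalence filtering, a concordance-index edge rule, and
  maximal-clique-centrality hub ranking (`build_network()`, `mcc_scores()`,
  `hub_intersection()`).
- **Gene-set scoring** — from-definition ssGSEA and preranked permutation
  GSEA (`ssgsea_score()`, `preranked_gsea()`).
- **Survival evaluation** — Kaplan–Meier/log-rank, Cox models (Efron ties),
  a points-based nomogram, IPCW time-dependent AUC, calibration curves and
  ICB-response utilities (`cox_fit()`, `build_nomogram()`,
  `time_dependent_auc()`, `calibration_curve()`).
- **A synthetic cohort generator** (`generate_cohort()`) that plants every
  structure above — two subtypes, coupled ligand–receptor pairs, a subtype
  hazard ratio of 5.583 and an age hazard ratio of 1.070/year — so the whole
  pipeline is testable offline.

See `vignette("efferotype-methods")` for the scientific background and the
reasoning behind each design choice.

## Worked example

Discover, classify and evaluate subtypes on a simulated 200-sample cohort:

```r
library(efferotype)

ch <- generate_cohort(cohort_config(seed = 1))
ch
#> <synthetic_cohort> 500 genes x 200 samples; 100 C1 / 100 C2; 10 planted + 30 decoy pairs

st <- nmf_subtype(log2_tpm(ch$expression), ch$signature_genes,
                  ranks = 2:4, n_restarts = 10, seed = 1,
                  max_iter = 150, tol = 1e-4)
st$selected_rank
#> [1] 2
st$cophenetic_by_rank
#>         2         3         4
#> 1.0000000 0.9864693 0.9672340
table(nmf = st$labels, truth = ch$truth_labels[names(st$labels)])
#>     truth
#> nmf   C1  C2
#>   C1 100   0
#>   C2   0 100
```

Transfer the subtypes with the shrunken-centroid classifier:

```r
ex <- subset_expr(log2_tpm(ch$expression), genes = ch$signature_genes)
sp <- stratified_split(names(st$labels), st$labels, 0.7, seed = 1)
fit <- fit_centroid_classifier(subset_expr(ex, samples = sp$train),
                               st$labels[sp$train], seed = 1)
pred <- predict_subtype(fit, subset_expr(ex, samples = sp$test))
roc_auc(pred$scores[, "C1"], st$labels[sp$test] == "C1")
#> [1] 1
```

Evaluate the survival impact of the discovered subtypes:

```r
cl <- ch$clinical
cl$subtype_nmf <- unname(st$labels[cl$sample_id])
km_logrank(cl, st$labels[cl$sample_id])$logrank_p
#> [1] 9.697716e-11

cx <- cox_fit(cl, c("subtype_nmf", "age"))
cx$table[, c("term", "hr", "ci_lower", "ci_upper")]
#>            term        hr  ci_lower  ci_upper
#> 1 subtype_nmfC2 0.1621568 0.1082646 0.2428757
#> 2           age 1.0698631 1.0571085 1.0827715

nom <- build_nomogram(cx, cl, horizons = 365)
time_dependent_auc(predict_nomogram(nom, cl)$lp, cl, 365)
#> [1] 0.8945356
```

C2's hazard ratio of 0.162 relative to C1 corresponds to a C1 hazard ratio of
1/0.162 ≈ 6.2, consistent with the planted 5.583 at this sample size, and the
age effect (1.070/year) is recovered almost exactly.

The single call `run_pipeline(pipeline_config(out_dir = "run1", seed = 1))`
executes all of the above end to end and writes per-stage artifacts plus an
md5-stamped `manifest.json`.

## License

MIT (see `LICENSE`).
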