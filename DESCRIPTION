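Package: efferotype
Title: Efferocytosis-Related Transcriptomic Subtyping of Glioma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and transfer of efferocytosis-related glioma
    transcriptomic subtypes. Provides consensus non-negative matrix
    factorization with cophenetic rank selection, a nearest-shrunken-centroid
    subtype classifier, a discretized ligand-receptor concordance network with
    maximal-clique-centrality hub ranking, rank-based single-sample and
    preranked gene-set enrichment, censored-survival evaluation (Cox models,
    nomogram, IPCW time-dependent AUC, calibration), and a synthetic cohort
    generator with planted subtype, hazard and co-expression structure so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    survival,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    fgsea,
    knitr,
    mclust,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
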