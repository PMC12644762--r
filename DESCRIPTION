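Package: nfkbgrn
Title: Bistable NF-kB Gene Regulatory Network Analysis of Breast Cancer
    Subtype Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mass-action modelling of the five-gene NF-kB circuit (p50, p65
    and the EMT transcription factors TWIST1, SLUG and SIP1) that underlies
    HER2-positive and triple-negative breast cancer expression phenotypes.
    Provides stationary-state enumeration with Jacobian eigenanalysis,
    exact (Gillespie) and tau-leaping stochastic simulation, quasi-potential
    attractor landscapes over the p50-p65 protein plane, first-passage
    analysis of spontaneous subtype transitions, perturbation scans of p65
    protein degradation, qPCR-based calibration utilities, Spearman
    correlation resampling against cohort-style data, and synthetic-data
    generators so that every stage of the pipeline can be exercised without
    external inputs. Results are returned as tibbles and ggplot2 layers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    deSolve,
    xml2,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
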