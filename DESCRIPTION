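Package: prevmapr
Title: Principled Prevalence Mapping from Stratified Household Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Small area estimation of the prevalence of binary indicators from
    stratified two-stage household surveys. Provides design-based direct
    estimation with Taylor-linearization variances, area-level (Fay-Herriot)
    smoothing with BYM2 spatial random effects and penalised-complexity priors,
    cluster-level beta-binomial models in five linear-predictor variants,
    urban/rural-aware aggregation from population rasters, model-evaluation
    diagnostics (over-smoothing screen, WAIC, exceedance probabilities), and a
    synthetic survey generator emulating a DHS-style stratified PPS design so
    the whole pipeline can be exercised with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
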