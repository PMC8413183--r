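Package: uveaclass
Title: Rule-Based Classification Criteria Machinery for Uveitis Research
Version: 0.1.0
Authors@R: person("uveaclass", "maintainers", email = "maintainers@uveaclass.org", role = c("aut", "cre"))
Description: A deterministic rule engine for research classification criteria
    of uveitic diseases (spondyloarthritis/HLA-B27-associated anterior
    uveitis, Fuchs uveitis syndrome, acute retinal necrosis) over a
    standardized clinical-findings data model with three-valued (Kleene)
    evaluation of incomplete workups, plus the criteria-derivation pipeline:
    shadow-feature (Boruta-style) selection, per-anatomic-class multinomial
    lasso classification, and distillation of the fitted model into a
    human-readable logical rule system that makes the same decision as the
    model on training and validation data.  Includes a synthetic labeled
    cohort generator for end-to-end testing, accuracy reporting with Wilson
    score confidence intervals, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
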