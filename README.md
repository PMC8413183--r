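# uveaclass

Machinery for **research classification criteria of uveitic diseases**: a
deterministic rule engine over a standardized clinical-findings data model,
and the machine-learning pipeline that derives such criteria from labeled
case collections.

Uveitis — intraocular inflammation, grouped anatomically as anterior,
intermediate, posterior and panuveitis — comprises ~25 clinically relevant
diseases, each rare enough that research depends on multi-center case
collections enrolled by *classification criteria*: specificity-oriented
rules ("criteria" plus dominating "exclusion criteria") that keep study
populations homogeneous.  `uveaclass` is for biostatisticians and clinical
researchers who want to

* apply published criteria mechanically and reproducibly to tabular case
  data with missing fields,
* represent criteria as data (a JSON rule DSL) rather than code, and
* exercise, on synthetic cohorts, the three-phase derivation process that
  produced them: per-anatomic-class model training, held-out validation,
  and distillation of the model into human-readable "final rules".

Three published rule sets ship with the package:
spondyloarthritis/HLA-B27-associated anterior uveitis, Fuchs uveitis
syndrome, and acute retinal necrosis.

## The models at the core

**Rule engine.** A rule set is a boolean expression tree over tri-state
clinical findings and test results, evaluated under strong Kleene
three-valued logic (AND = min, OR = max over F < U < T; a predicate on an
unassessed field is U).  Per disease the verdict is `excluded` (some
exclusion definitely true — exclusion dominates), `classified` (criteria
definitely true, no exclusion true), `indeterminate` (criteria unknown) or
`criteria_not_met`.  Unknown never classifies and never excludes.

**Derivation pipeline.** Cases are recoded to binary indicators (unknown
as its own indicator, cumulative indicators for 0–4 severity grades).
Decisive features are selected by a shadow-feature (Boruta-style)
procedure: real features must beat the best column-permuted copy of the
feature set, scored by out-of-bag permutation importance of a bagged-tree
ensemble, with a Bonferroni-corrected binomial test over iterations.  The
classifier is a multinomial logistic regression with lasso penalty,

&nbsp;&nbsp;&nbsp;&nbsp;min<sub>β₀,β</sub>  −(1/n) Σᵢ log p(yᵢ | xᵢ; β₀, β) + λ‖β‖₁,

fit per anatomic class (λ by stratified cross-validation with the 1-SE
rule).  Phase III fits an unpruned decision-tree student on the *model's*
predictions and converts its leaves to simplified disjunctive-normal-form
rules that provably make the same decision as the model on the cohort —
agreement 1.0 or an explicit disagreement list, never approximation.
Accuracy reports mirror the published format: overall accuracy per
stratum with Wilson 95% CIs and per-disease misclassification rates
(1 − recall).

## Worked example

Classify a patient against the three shipped rule sets:

```r
library(uveaclass)
rules <- uv_rulesets()   # spa_hla_b27, fuchs_uveitis, arn

patient <- uv_case("P-001", "anterior",
  course = "recurrent_acute", laterality = "unilateral",
  findings = list(anterior_chamber_cells = list(value = "present", grade = 2),
                  vitreous_cells_anterior = "absent"),
  tests = list(hla_b27 = "positive",
               syphilis_serology_treponemal = "negative",
               pcr_aqueous_cmv = "negative", pcr_aqueous_hsv = "negative",
               pcr_aqueous_vzv = "negative"))

classify_case(patient, rules)
#> <uv_classification> P-001
#>   spa_hla_b27          classified       criteria=T exclusions=[F,U,F]
#>   fuchs_uveitis        indeterminate    criteria=U exclusions=[F,U,F]
#>   arn                  indeterminate    criteria=U exclusions=[F,U]
```

The patient meets the SpA/HLA-B27 criteria; the `U` in the exclusion
trace records that the sarcoidosis workup (chest imaging / biopsy) was
never done — absence of evidence does not exclude, but the trace lets you
demand a completed workup.  Fuchs and ARN stay `indeterminate` because
their discriminating findings were not assessed.

Run the full derivation pipeline on a noisy synthetic cohort (5% flipped
fields, 600 cases, three anterior diseases):

```r
config <- list(seed = 42,
  simulate = list(rulesets = c("spa_hla_b27", "fuchs_uveitis", "synthetic_viral_au"),
                  n_cases = 600, flip_noise = 0.05, train_fraction = 2/3),
  boruta = list(n_iter = 30, n_trees = 100))
report <- run_pipeline(config, out_dir = "pipeline_out")
report$strata$anterior$validation$accuracy
```

which prints (seed 42):

```
validation accuracy 0.975 (95% CI 0.943-0.989), lambda 0.00578
             disease  n misclassification      ci_low    ci_high
1      fuchs_uveitis 71        0.02816901 0.007759264 0.09701500
2        spa_hla_b27 64        0.00000000 0.000000000 0.05662406
3 synthetic_viral_au 65        0.04615385 0.015819840 0.12713847
   overall      train validation
         1          1          1
```

— validation accuracy of the lasso model with its Wilson interval,
per-disease misclassification rates, and the distilled rules' exact
agreement with the model on both splits.  `pipeline_out/` receives the
cohort CSV, the model JSON, the distilled rules in the rule DSL, the
confusion matrix and the full JSON report.  A command-line interface
wraps the same steps (`inst/cli/uveaclass.R`:
`classify | simulate | derive | distill | evaluate | run`).

## Package layout

```
R/                     data model, engine, DSL, generator, selection,
                       lasso, distillation, reporting, pipeline, CLI
src/forest.cpp         bagged-tree importance scorer (Rcpp)
inst/extdata/          vocabulary registry + shipped rule sets (JSON)
inst/cli/uveaclass.R   command-line launcher
tests/testthat/        unit, property and acceptance suites
scripts/acceptance.R   acceptance report entry point
vignettes/             methods vignette
```
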