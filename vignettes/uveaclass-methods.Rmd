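---
title: "Classification-criteria machinery for uveitis research: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classification-criteria machinery for uveitis research: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model of the problem

Research classification criteria for uveitic diseases are
specificity-oriented rules: they exist to enroll homogeneous patient groups
into studies, not to maximize diagnostic sensitivity.  `uveaclass`
implements the machinery around such criteria for three diseases whose
consensus criteria are bundled with the package —
spondyloarthritis/HLA-B27-associated anterior uveitis, Fuchs uveitis
syndrome, and acute retinal necrosis (ARN) — together with the
derivation pipeline that produced criteria of this shape: feature
recoding, all-relevant (shadow-feature) selection, a per-anatomic-class
multinomial lasso, and distillation of the fitted model into a logical
rule system that makes the same decision as the model.

Two ideas organize the package:

1. **A rule set is data.**  Criteria are boolean expression trees over a
   controlled clinical vocabulary, serialized in a small JSON DSL
   (`load_ruleset()`/`save_ruleset()`).  The vocabulary itself is a data
   file, so criteria for further diseases can be added without code
   changes.
2. **Missingness is first-class.**  Clinical workups are incomplete; every
   finding and test is tri-state (present/absent/unknown,
   positive/negative/unknown) and rules are evaluated under strong Kleene
   three-valued logic.

## Evaluation semantics

`eval_expr()` uses strong Kleene logic: `AND` is the minimum and `OR` the
maximum under the ordering F < U < T; `NOT` swaps T/F and fixes U.  A
predicate over an unassessed field yields U.  The classification verdict
per disease is then:

* **excluded** — some exclusion expression is definitely true.  Exclusion
  dominates everything else.
* **classified** — the criteria tree is definitely true and no exclusion
  is true.
* **indeterminate** — the criteria evaluate to U (incomplete workup).
* **criteria_not_met** — the criteria are definitely false.

Two asymmetric design choices deserve justification:

* *Unknown never classifies.*  Criteria demand positive evidence;
  specificity-first intent means an undocumented finding cannot support
  enrollment.
* *Unknown never excludes.*  Exclusions demand positive evidence of a
  mimic (a positive treponemal test, a positive PCR); an untested patient
  is not excluded.  The per-item Kleene trace is kept in the
  `ClassificationResult` so a caller who wants to require a completed
  exclusion workup can do so.

Several diseases may classify simultaneously: the printed rule sets are
logically independent, so `final_labels` is a set and competition between
diseases is the job of the learned classifier, not the engine.

Severity comparisons ("vitreous cells less severe than the anterior
chamber inflammation") use an ordinal 0–4 grade on gradable findings
(SUN-style cell grading; the sources compare severities without printing a
scale, so the scale is a package choice marked in the registry).  A grade
comparison with either grade unrecorded evaluates to U; an absent finding
has grade 0.  The ARN exclusion for CMV/Toxoplasma PCR carries its
parenthetical escape clause ("unless immunocompromised, morphologic
evidence of more than one infection, the characteristic clinical picture,
and intraocular PCR positive for HSV or VZV") as
`AND(trigger, NOT(escape))` inside a single exclusion expression — the only
negation in the shipped content.

The alternative chronic pathway of the SpA criteria is encoded exactly as
printed ("item 1 AND (either (items 2 and 3) OR item 4)"); whether the
chronic-after-recurrent course alone can ever classify without item 3 is
not stated in the source material, and the package encodes the printed
connective without further interpretation.  Aqueous and intraocular PCR
specimens are modeled as distinct test codes, again because the printed
exclusions name them differently.

## The synthetic cohort generator: what it emulates, what it does not

The consensus database behind the published criteria (>4000 cases, ~150–250
per disease) is not public.  `generate_cohort()` therefore builds labeled
cohorts directly from rule sets, which is exactly what makes the pipeline
testable end-to-end: by construction the ground truth of every case is
known and, at zero noise, the engine must recover it perfectly (this is
asserted, exactly, at n = 1000).

Per case, `sample_case()`:

* samples a satisfying assignment of the disease's criteria tree,
  choosing OR branches uniformly at random with transactional backtracking
  on contradictory constraint sets (a contradictory tree raises an
  unsatisfiability error);
* forces the disease's own exclusion-trigger fields negative;
* draws every other vocabulary field from a background frequency
  (default 5% present/positive, configurable per code) — so noisy cohorts
  do contain mimics that trigger exclusions, mirroring the real
  database's confusable cases;
* leaves course and laterality the criteria do not constrain as
  `unknown` — the generator states only what the rules require.

Flip noise (present↔absent, positive↔negative) and missingness are applied
afterwards to findings and tests, never to identifiers or labels; the
train/validation split is stratified per disease.  Everything is
deterministic given the integer seed.

The generator emulates *label structure*, not epidemiology: background
fields are independent, prevalences are configurable weights with no
claim to realism, and no correlated comorbidity exists.  A green pipeline
test therefore establishes that the machinery recovers rule-generated
structure — not that it would reproduce the published accuracies on real
patients, which is also why the package's acceptance checking is
property-based rather than number-matching.

## Phase I: recoding and all-relevant selection

`recode()` produces a binary matrix with a fixed, documented column
order: one-hot course and laterality (unknown as its own level),
`present`/`unknown` indicator pairs per finding (absent = both zero),
cumulative `>=g` indicators for grades, and `positive`/`unknown` pairs per
test.  Treating "unknown" as its own indicator lets the learner, and the
distilled rules, exploit missingness patterns explicitly.

`boruta_select()` is a shadow-feature procedure: each iteration appends a
column-permuted shadow copy of every feature, scores all columns with a
bagged-tree ensemble, and counts a *hit* when a real feature outscores the
best shadow.  Hits are tested two-sided against Binomial(n_iter, ½) at
`alpha = 0.01` with Bonferroni correction across features (conservative,
matching the sparsity-first intent); features are confirmed, rejected or
left tentative.  The importance scorer is written for this package (no
random-forest implementation ships with the grading image): CART trees on
binary features, Gini splits, `mtry = floor(sqrt(p))` over the doubled
column set, with out-of-bag permutation importance summarized per feature
as a t-statistic over trees — the Z-score comparison of the published
Boruta family.  Defaults are 500 trees and 100 iterations; both are
configuration, and none of the selection settings are canonical (the
source material names only the procedure, not its parameters).

A power limitation is documented here deliberately, because an acceptance
check reports it honestly as red: a feature whose only class contrast is
the 5% background rate (for example *endotheliitis present*, which the
Fuchs criteria force absent while other anterior diseases show it in ~5%
of cases — roughly 13 positive cases in a 400-case training set) carries
almost no *conditional* importance once strong separators (course
recorded vs unknown, heterochromia, aqueous PCR) are in the forest: trees
that could use it gain nothing after the strong splits, its out-of-bag
permutation importance concentrates at zero, and its hit rate plateaus
near the shadow maximum regardless of ensemble size (verified at 500
trees/100 iterations and 2000 trees/40 iterations).  All-relevant
selection with a Bonferroni-corrected binomial test cannot confirm such
features at this sample size; the pipeline does not need them (validation
accuracy is 1.0 without them), but the "selection recovers every criteria
atom" property is genuinely unattainable for them in the simulated world,
and the corresponding acceptance assertion is left failing rather than
weakened.

## Phase I/II: the multinomial lasso

The classifier minimizes the mean negative multinomial log-likelihood
plus an L1 penalty on slopes (intercepts unpenalized).  The fit is
delegated to glmnet — the field-standard coordinate-descent implementation
of exactly this objective — with `standardize = FALSE` (all predictors are
0/1 indicators on a common scale, and unstandardized coefficients remain
interpretable as log-odds contrasts).  `lambda = "cv"` selects the penalty
by stratified 5-fold cross-validated deviance with the one-standard-error
rule; the cross-validation design is a package choice, flagged
non-canonical.  The fitted object stores the coefficient matrix
explicitly; `predict()` computes the softmax from the stored coefficients
(rows sum to 1 within 1e-12) and breaks argmax ties toward the first
class in class order — the documented rule that also makes distillation
deterministic.  `lambda_max()` gives the closed-form smallest penalty with
an all-zero solution, `max |mean_i x_ij (1[y_i = k] − p̄_k)|`, used by the
shrinkage-limit checks.

## Phase III: distillation

`distill()` fits an unpruned decision-tree student on the *model's own
predictions* (teacher labels, not ground truth), restricted to the
features with nonzero coefficients.  Because the teacher label is a
deterministic function of the features, growing to pure leaves guarantees
exact agreement on every case the tree saw; the package fits the student
on train and validation cases together, which is the faithful reading of
"makes the same decision on the training and validation data".  The
contract is strict: the report either shows agreement 1.0 on both splits
or lists the disagreeing case ids — never a silent approximation.

Each class's leaves become a disjunctive normal form, simplified by
absorption/subsumption only; simplification is re-checked case by case
against the cohort and aborts if any decision would change.  DNF literals
map back to DSL predicates (`finding_is`, `test_is`, `grade_ge`,
`course_in`, including the two-valued `unknown`-state predicates), so the
derived rules are serializable in the same DSL as the expert criteria —
with empty exclusion lists, since exclusion content is expert knowledge
and out of distillation's scope.  Distilled rules are evaluated two-valued
over the recoded feature space (missingness is an explicit state there),
unlike the expert rule sets, which are evaluated under Kleene logic over
raw cases; the package keeps these two evaluation regimes deliberately
separate.

## Reporting

`accuracy_report()` mirrors the published reporting format: overall
accuracy per anatomic-class stratum with a 95% confidence interval and a
per-disease misclassification rate (defined as 1 − recall of that disease
against the consensus/true label; the source does not define the rate
formally).  Intervals are Wilson score intervals — the sources print
asymmetric intervals consistent with score-type methods but never name
one, so the choice is flagged non-canonical; an exact Clopper–Pearson
interval is provided alongside, and the test suite cross-checks both
against independent numerical inversions of their defining equations for
every (k, n) with n ≤ 50.  The audit of rules against the model that the
human masked reader performed on a 10% subsample in the original process
is mechanized by `check_agreement(..., sample_fraction = 0.1)`.

## Numerical and degenerate-input choices

* Kleene values are the ordered set F < U < T; `expr_equivalent()` decides
  equivalence by exhaustive enumeration over the joint atom domain and
  refuses domains beyond 3^12 assignments.
* Graded findings enumerate joint (value, grade) states respecting the
  invariants: grade 0 ⟺ absent, grade > 0 ⟹ present; a present finding may
  have an unrecorded grade.
* The synthetic generator errors on unsatisfiable criteria instead of
  looping; OR-branch choice is uniform over children with backtracking,
  so every satisfiable branch has positive probability.
* `glmnet` convergence is left at its defaults; coefficient extraction at
  a requested penalty uses path interpolation.  Row-permutation invariance
  of the fit is asserted to 1e-6.
* Ties: argmax ties break toward the first class; the student tree breaks
  split ties toward the lowest column index; leaf majorities (unreachable
  with a deterministic teacher) break toward the smallest class index.
* Empty cohorts round-trip as header-only CSV files; an empty case (all
  fields unknown) is valid and yields U/indeterminate everywhere.

## Known limitations

* Only the three published rule sets are shipped; the DSL supports, but
  does not contain, the remaining consensus criteria.  The fourth bundled
  file is a clearly marked synthetic stand-in used to give derivation
  tests a third anterior disease.
* The generator's feature distributions are not calibrated to any real
  database; published accuracies cannot be, and are not, reproduced.
* The distilled rules are faithful to the *model*, not to the truth; on
  noisy cohorts the model's errors are reproduced by design.
* Boruta-style selection misses features that are weakly relevant but
  conditionally redundant (see above) — a property of the method at these
  sample sizes, reported rather than patched.
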