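# Distillation: student tree, DNF rules, agreement contract.

# small labeled anterior cohort and a model fit on it
distill_fixture <- function(n = 240, seed = 21, lambda = 0.01) {
  rs3 <- uv_rulesets(c("spa_hla_b27", "fuchs_uveitis", "synthetic_viral_au"))
  feats <- recode(generate_cohort(cohort_spec(rs3, n_cases = n, seed = seed)))
  tr <- feats$split == "train"
  model <- fit_multinomial_lasso(feats$x[tr, ], droplevels(feats$labels[tr]),
                                 lambda = lambda)
  list(feats = feats, model = model)
}

test_that("a one-feature teacher distills to that single predicate", {
  # hand-built model: class b iff heterochromia present
  cols <- uveaclass:::feature_columns()
  beta <- matrix(0, length(cols), 2, dimnames = list(cols, c("a", "b")))
  beta["heterochromia=present", ] <- c(-4, 4)
  model <- structure(list(classes = c("a", "b"), feature_names = cols,
                          beta = beta, intercepts = c(a = 1, b = -1),
                          lambda = 0.1,
                          selected_features = "heterochromia=present"),
                     class = "uv_model")
  rs3 <- uv_rulesets(c("spa_hla_b27", "fuchs_uveitis", "synthetic_viral_au"))
  feats <- recode(generate_cohort(cohort_spec(rs3, n_cases = 120, seed = 33)))
  feats$labels <- factor(ifelse(feats$x[, "heterochromia=present"] == 1, "b", "a"))
  d <- distill(model, feats)
  expect_identical(unname(d$agreement["overall"]), 1)
  # rule for b is exactly the heterochromia predicate; rule for a its negation
  expect_true(expr_equivalent(d$rules$b, finding_is("heterochromia", "present")))
  expect_true(expr_equivalent(d$rules$a,
                              rx_not(finding_is("heterochromia", "present"))))
})

test_that("a constant teacher yields the TRUE rule with agreement 1", {
  cols <- uveaclass:::feature_columns()
  beta <- matrix(0, length(cols), 2, dimnames = list(cols, c("a", "b")))
  model <- structure(list(classes = c("a", "b"), feature_names = cols,
                          beta = beta, intercepts = c(a = 5, b = 0),
                          lambda = 1, selected_features = character(0)),
                     class = "uv_model")
  rs3 <- uv_rulesets(c("spa_hla_b27", "fuchs_uveitis"))
  feats <- recode(generate_cohort(cohort_spec(rs3, n_cases = 60, seed = 8)))
  d <- distill(model, feats)
  expect_identical(d$rules$a$kind, "true")
  expect_identical(unname(d$agreement["overall"]), 1)
  expect_length(d$disagreements, 0L)
})

test_that("distilled rules agree with the model on both splits and stay sound under simplification", {
  for (seed in c(21, 22)) {
    fx <- distill_fixture(seed = seed)
    d <- distill(fx$model, fx$feats)
    expect_identical(unname(d$agreement["train"]), 1)
    expect_identical(unname(d$agreement["validation"]), 1)
    expect_length(d$disagreements, 0L)
    # simplification never grows the rule system
    expect_true(all(d$complexity <= d$raw_complexity))
  }
})

test_that("check_agreement: self-agreement 1, negated teacher 0, subsample size", {
  fx <- distill_fixture()
  d <- distill(fx$model, fx$feats)
  chk <- check_agreement(d$rules, fx$model, fx$feats)
  expect_identical(unname(chk$agreement["overall"]), 1)

  # a two-class problem with rules swapped disagrees everywhere
  cols <- uveaclass:::feature_columns()
  beta <- matrix(0, length(cols), 2, dimnames = list(cols, c("a", "b")))
  beta["heterochromia=present", ] <- c(-4, 4)
  model2 <- structure(list(classes = c("a", "b"), feature_names = cols,
                           beta = beta, intercepts = c(a = 1, b = -1),
                           lambda = 0.1,
                           selected_features = "heterochromia=present"),
                      class = "uv_model")
  pred <- finding_is("heterochromia", "present")
  swapped <- list(a = pred, b = rx_not(pred))   # negation of the teacher
  chk2 <- check_agreement(swapped, model2, fx$feats)
  expect_identical(unname(chk2$agreement["overall"]), 0)

  set.seed(14)
  chk3 <- check_agreement(d$rules, fx$model, fx$feats, sample_fraction = 0.1)
  expect_equal(chk3$n, round(0.1 * nrow(fx$feats$x)))
})

test_that("distill validates the feature/model match", {
  fx <- distill_fixture()
  feats2 <- fx$feats
  colnames(feats2$x) <- paste0("x_", colnames(feats2$x))
  expect_error(distill(fx$model, feats2), "lacks columns")
})
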