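# Three-valued evaluation and classification semantics.

test_that("eval_expr follows strong Kleene semantics", {
  # one definitely-true, one definitely-false and one unknown leaf
  cs <- uv_case("k", findings = list(heterochromia = "present",
                                     endotheliitis = "absent"))
  T_ <- finding_is("heterochromia")          # evaluates T
  F_ <- finding_is("endotheliitis")          # present expected, absent -> F
  U_ <- finding_is("stellate_keratic_precipitates")  # unrecorded -> U
  expect_identical(eval_expr(T_, cs), "T")
  expect_identical(eval_expr(F_, cs), "F")
  expect_identical(eval_expr(U_, cs), "U")
  expect_identical(eval_expr(rx_or(T_, U_), cs), "T")
  expect_identical(eval_expr(rx_and(T_, U_), cs), "U")
  expect_identical(eval_expr(rx_not(U_), cs), "U")
  expect_identical(eval_expr(rx_and(F_, U_), cs), "F")
  expect_identical(eval_expr(rx_or(F_, U_), cs), "U")
  expect_identical(eval_expr(rx_not(T_), cs), "F")
  # grade comparison with an unknown grade is U
  cs2 <- uv_case("k2", findings = list(
    anterior_chamber_cells = "present",   # present, grade unrecorded
    vitreous_cells_anterior = list(value = "present", grade = 1)))
  expect_identical(
    eval_expr(grade_lt("vitreous_cells_anterior", "anterior_chamber_cells"), cs2),
    "U")
})

test_that("heterochromia alone satisfies the Fuchs item-3 disjunction under unknowns", {
  rs <- uv_rulesets("fuchs_uveitis")[[1]]
  item3 <- rs$criteria$children[[3]]
  cs <- uv_case("h", findings = list(heterochromia = "present"))
  expect_identical(eval_expr(item3, cs), "T")  # OR(T, U) = T
})

test_that("an expression over entirely unknown fields evaluates U, and the empty case never classifies", {
  rs <- uv_rulesets()
  empty <- uv_case("empty")
  for (one in rs) {
    expect_identical(eval_expr(one$criteria, empty), "U")
    res <- classify_case(empty, one)
    expect_true(res$verdicts[[one$disease_id]] %in%
                  c("indeterminate", "criteria_not_met"))
  }
  expect_length(classify_case(empty, rs)$final_labels, 0L)
})

test_that("classification is deterministic and traces every rule item", {
  rs <- uv_rulesets()
  cs <- spa_base()
  r1 <- classify_case(cs, rs)
  r2 <- classify_case(cs, rs)
  expect_identical(r1, r2)
  expect_identical(r1$final_labels, "spa_hla_b27")
  tr <- r1$trace$spa_hla_b27
  expect_identical(tr$criteria, "T")
  expect_length(tr$exclusions, 3L)
  expect_length(r1$trace$arn$exclusions, 2L)
})

test_that("exclusion dominance: forcing any exclusion true never leaves a case classified", {
  rs <- uv_rulesets()
  # the ARN escape clause is pinned false (immunocompetent host) so that a
  # positive intraocular PCR really does make exclusion 2 true
  bases <- list(spa_base(), fuchs_base(),
                vignette(arn_base(), tests = list(immunocompromised = "negative")))
  # every positive-polarity trigger leaf of every exclusion, one at a time
  for (i in seq_along(rs)) {
    base <- bases[[i]]
    for (ex in rs[[i]]$exclusions) {
      leaves <- uveaclass:::trigger_leaves(ex)
      for (k in seq_len(nrow(leaves))) {
        mutated <- if (leaves$kind[k] == "finding_is")
          vignette(base, findings = stats::setNames(list(leaves$value[k]),
                                                    leaves$code[k]))
        else vignette(base, tests = stats::setNames(list(leaves$value[k]),
                                                    leaves$code[k]))
        res <- classify_case(mutated, rs[[i]])
        expect_identical(unname(res$verdicts[1]), "excluded",
                         label = paste(rs[[i]]$disease_id, leaves$code[k]))
      }
    }
  }
})

test_that("resolving unknown fields never demotes a classified verdict to indeterminate", {
  # Kleene monotonicity on the negation-free criteria: start from a
  # classified vignette, blank one non-essential field to unknown, then
  # resolve it both ways; the verdict must stay classified or become
  # excluded, never indeterminate/criteria_not_met -> indeterminate drift.
  rs <- uv_rulesets()
  bases <- list(spa_base(), fuchs_base(), arn_base())
  set.seed(71)
  for (i in seq_along(rs)) {
    base <- bases[[i]]
    stopifnot(classify_case(base, rs[[i]])$verdicts[1] == "classified")
    for (code in uveaclass:::uv_test_codes()) {
      blanked <- vignette(base, tests = stats::setNames(list(NULL), code))
      v0 <- classify_case(blanked, rs[[i]])$verdicts[1]
      for (val in c("positive", "negative")) {
        resolved <- vignette(blanked, tests = stats::setNames(list(val), code))
        v1 <- classify_case(resolved, rs[[i]])$verdicts[1]
        if (v0 == "classified")
          expect_true(v1 %in% c("classified", "excluded"),
                      label = paste(rs[[i]]$disease_id, code, val))
      }
    }
  }
})
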