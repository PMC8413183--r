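# Synthetic cohort generator: soundness, determinism, noise behaviour.

test_that("sample_case always satisfies its rule set pre-noise", {
  rs <- uv_rulesets()
  set.seed(31)
  for (one in rs) {
    for (i in 1:50) {
      cs <- sample_case(one, paste0("s", i))
      expect_identical(validate_case(cs), character(0))
      expect_true(one$disease_id %in% classify_case(cs, one)$final_labels)
    }
  }
})

test_that("ARN sampling exercises both the PCR branch and the clinical-picture branch", {
  arn <- uv_rulesets("arn")[[1]]
  set.seed(92)
  pcr_branch <- 0L; clinical_branch <- 0L
  pcr_codes <- c("pcr_aqueous_hsv", "pcr_aqueous_vzv",
                 "pcr_vitreous_hsv", "pcr_vitreous_vzv")
  for (i in 1:200) {
    cs <- sample_case(arn, paste0("a", i), background_rate = 0)
    if (any(vapply(pcr_codes, function(code) case_value(cs, code), "") == "positive"))
      pcr_branch <- pcr_branch + 1L
    if (case_value(cs, "confluent_retinitis") == "present" &&
        case_value(cs, "retinal_vascular_sheathing_or_occlusion") == "present" &&
        case_value(cs, "more_than_minimal_vitritis") == "present")
      clinical_branch <- clinical_branch + 1L
  }
  expect_gt(pcr_branch, 0L)
  expect_gt(clinical_branch, 0L)
})

test_that("unsatisfiable criteria raise an error", {
  contradiction <- rule_set("impossible", "impossible", "anterior",
                            rx_and(finding_is("heterochromia"),
                                   rx_not(finding_is("heterochromia"))))
  set.seed(1)
  expect_error(sample_case(contradiction, "x"), "unsatisfiable")
})

test_that("generate_cohort is deterministic, labeled, and exact at zero noise", {
  rs <- uv_rulesets()
  spec <- cohort_spec(rs, n_cases = 120, seed = 7)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  expect_length(a, 120L)
  expect_false(any(is.na(uveaclass:::cohort_labels(a))))
  expect_identical(engine_accuracy(a, rs), 1)
  expect_length(generate_cohort(cohort_spec(rs, n_cases = 0, seed = 1)), 0L)
})

test_that("the split is stratified within one case per disease", {
  rs <- uv_rulesets()
  for (seed in 1:3) {
    coh <- generate_cohort(cohort_spec(rs, n_cases = 150, seed = seed,
                                       train_fraction = 0.7))
    labs <- uveaclass:::cohort_labels(coh)
    for (d in unique(labs)) {
      n_d <- sum(labs == d)
      n_train <- sum(labs == d & coh$split == "train")
      expect_lte(abs(n_train - 0.7 * n_d), 1)
    }
  }
})

test_that("flip noise strictly degrades engine accuracy at n = 1000", {
  rs <- uv_rulesets()
  for (seed in 1:10) {
    coh <- generate_cohort(cohort_spec(rs, n_cases = 1000, flip_noise = 0.05,
                                       seed = seed))
    expect_lt(engine_accuracy(coh, rs), 1)
  }
})

test_that("cohort_spec validates probabilities and the split fraction", {
  rs <- uv_rulesets("arn")
  expect_error(cohort_spec(rs, 10, train_fraction = 1.0), "strictly between")
  expect_error(cohort_spec(rs, 10, train_fraction = 0), "strictly between")
  expect_error(cohort_spec(rs, 10, flip_noise = 1.5))
  expect_error(cohort_spec(rs, 10, weights = -1))
})
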