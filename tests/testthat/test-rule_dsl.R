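# The JSON rule DSL: shipped content, round-trips, schema errors.
# (random_expr / random_ruleset come from helper-random.R)

test_that("shipped rule sets load with the printed structure", {
  spa <- uv_rulesets("spa_hla_b27")[[1]]
  expect_identical(spa$anatomic_class, "anterior")
  expect_identical(spa$criteria$kind, "and")   # one top-level criteria tree
  expect_length(spa$exclusions, 3L)            # exclusions 1-3
  fuchs <- uv_rulesets("fuchs_uveitis")[[1]]
  expect_length(fuchs$criteria$children, 4L)   # items 1-4
  expect_length(fuchs$exclusions, 3L)
  arn <- uv_rulesets("arn")[[1]]
  expect_identical(arn$anatomic_class, "infectious_post_pan")
  expect_length(arn$exclusions, 2L)
  # ARN exclusion 2 carries the encoded escape clause
  expect_identical(arn$exclusions[[2]]$children[[2]]$kind, "not")
})

test_that("save/load round-trips shipped and random rule sets structurally", {
  path <- withr::local_tempfile(fileext = ".json")
  for (rs in uv_rulesets(c("spa_hla_b27", "fuchs_uveitis", "arn"))) {
    save_ruleset(rs, path)
    expect_identical(load_ruleset(path), rs)
  }
  set.seed(202)
  for (i in seq_len(200)) {
    rs <- random_ruleset(sprintf("rnd_%03d", i))
    save_ruleset(rs, path)
    expect_identical(load_ruleset(path), rs)
  }
})

test_that("schema violations and unknown codes are rejected with a JSON path", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"disease_id":"x","disease_name":"x","anatomic_class":"anterior",
    "criteria":{"finding_is":{"code":"made_up_sign","value":"present"}}}', path)
  expect_error(load_ruleset(path), "made_up_sign")
  writeLines('{"disease_id":"x","disease_name":"x","anatomic_class":"anterior",
    "criteria":{"frobnicate":[]}}', path)
  expect_error(load_ruleset(path), "\\$\\.criteria.*frobnicate")
  writeLines('{"disease_name":"x","anatomic_class":"anterior",
    "criteria":{"true":{}}}', path)
  expect_error(load_ruleset(path), "disease_id")
})

test_that("expr_equivalent: laws, refusal, and the printed main connective vs its DNF", {
  x <- finding_is("heterochromia")
  y <- finding_is("endotheliitis")
  expect_true(expr_equivalent(rx_or(x, rx_and(x, y)), x))     # absorption
  expect_false(expr_equivalent(x, rx_not(x)))
  expect_true(expr_equivalent(rx_not(rx_and(x, y)),
                              rx_or(rx_not(x), rx_not(y))))   # De Morgan
  # exhaustive enumeration refuses oversized domains
  big <- do.call(rx_or, lapply(uveaclass:::uv_test_codes()[1:13], test_is))
  expect_error(expr_equivalent(big, big), "domain too large")

  # the main connective "#1 AND (either (#2 and #3) OR #4)" against a
  # hand-rewritten DNF: (#1 and #2 and #3) OR (#1 and #4)
  spa <- uv_rulesets("spa_hla_b27")[[1]]
  i1 <- spa$criteria$children[[1]]
  alt <- spa$criteria$children[[2]]
  i23 <- alt$children[[1]]
  i4 <- alt$children[[2]]
  dnf <- rx_or(rx_and(i1, i23$children[[1]], i23$children[[2]]),
               rx_and(i1, i4))
  expect_true(expr_equivalent(spa$criteria, dnf))
})
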