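# Recoding, shadow-feature selection and the multinomial lasso.

test_that("recode implements the documented one-hot/cumulative encoding", {
  cs <- uv_case("r1", course = "acute", laterality = "unknown",
                findings = list(
                  anterior_chamber_cells = list(value = "present", grade = 2),
                  heterochromia = "present",
                  endotheliitis = "absent"),
                tests = list(hla_b27 = "positive"),
                true_label = "d1")
  f <- recode(uv_cohort(list(cs)))
  row <- f$x[1, ]
  expect_identical(unname(row[c("heterochromia=present", "heterochromia=unknown")]),
                   c(1L, 0L))
  expect_identical(unname(row[c("endotheliitis=present", "endotheliitis=unknown")]),
                   c(0L, 0L))
  expect_identical(unname(row[c("stellate_keratic_precipitates=present",
                                "stellate_keratic_precipitates=unknown")]),
                   c(0L, 1L))
  # grade 2 of 4 -> cumulative [1, 1, 0, 0]
  expect_identical(unname(row[paste0("anterior_chamber_cells>=", 1:4)]),
                   c(1L, 1L, 0L, 0L))
  expect_identical(unname(row["course=acute"]), 1L)
  expect_identical(unname(row["course=unknown"]), 0L)
  expect_identical(unname(row["laterality=unknown"]), 1L)
  expect_identical(unname(row[c("hla_b27=positive", "hla_b27=unknown")]), c(1L, 0L))
  expect_true(all(f$x %in% 0:1))
})

test_that("recode refuses unlabeled cohorts", {
  expect_error(recode(uv_cohort(list(uv_case("u")))), "true_label")
})

test_that("boruta confirms a decisive feature and rejects noise (10 seeds, >= 9 agree)", {
  ok <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    x <- matrix(rbinom(200 * 10, 1, 0.5), nrow = 200,
                dimnames = list(NULL, paste0("f", 1:10)))
    y <- factor(x[, 1])
    sel <- boruta_select(x, y, n_iter = 100, n_trees = 100, seed = seed + 100)
    good <- sel$status[1] == "confirmed" &&
      all(sel$status[-1] == "rejected")     # no tentatives at n_iter = 100
    ok <- ok + good
  }
  expect_gte(ok, 9L)
})

test_that("pure-noise features are never confirmed and n_iter = 0 leaves all tentative", {
  set.seed(5)
  x <- matrix(rbinom(500 * 8, 1, 0.3), nrow = 500,
              dimnames = list(NULL, paste0("n", 1:8)))
  y <- factor(rbinom(500, 1, 0.5))
  sel <- boruta_select(x, y, n_iter = 50, n_trees = 100, seed = 6)
  expect_false(any(sel$status == "confirmed"))
  sel0 <- boruta_select(x, y, n_iter = 0, seed = 6)
  expect_true(all(sel0$status == "tentative"))
  expect_error(boruta_select(x, factor(rep("a", 500)), n_iter = 1), "two classes")
})

sep_data <- function(n = 80, seed = 9) {
  set.seed(seed)
  x <- cbind(sig = rep(0:1, each = n / 2),
             noise1 = rbinom(n, 1, 0.5), noise2 = rbinom(n, 1, 0.5))
  list(x = x, y = factor(ifelse(x[, "sig"] == 1, "b", "a")))
}

test_that("full shrinkage: lambda >= lambda_max zeroes every coefficient", {
  d <- sep_data()
  lmax <- lambda_max(d$x, d$y)
  m <- fit_multinomial_lasso(d$x, d$y, lambda = lmax * 1.0001)
  expect_true(all(m$beta == 0))
  expect_length(m$selected_features, 0L)
  # null-model predictions equal training class frequencies
  pr <- predict(m, d$x)$prob
  expect_equal(unname(pr[1, ]), unname(as.vector(table(d$y)) / length(d$y)),
               tolerance = 1e-6)
})

test_that("a separating feature gets the right sign and perfect training accuracy", {
  d <- sep_data()
  m <- fit_multinomial_lasso(d$x, d$y, lambda = 0.001)
  expect_gt(m$beta["sig", "b"] - m$beta["sig", "a"], 0)  # correct direction
  pred <- predict(m, d$x)$label
  expect_identical(as.character(pred), as.character(d$y))
  # unregularized single-predictor oracle agrees on the sign
  oracle <- stats::glm(d$y ~ d$x[, "sig"], family = stats::binomial)
  expect_gt(suppressWarnings(stats::coef(oracle)[2]), 0)
})

test_that("fitting is invariant to row permutation", {
  d <- sep_data(n = 60, seed = 10)
  m1 <- fit_multinomial_lasso(d$x, d$y, lambda = 0.01)
  set.seed(11)
  perm <- sample(nrow(d$x))
  m2 <- fit_multinomial_lasso(d$x[perm, ], d$y[perm], lambda = 0.01)
  expect_lt(max(abs(m1$beta - m2$beta)), 1e-6)
  expect_lt(max(abs(m1$intercepts - m2$intercepts)), 1e-6)
})

test_that("sparsity is monotone non-increasing along a 10-point lambda path", {
  rs3 <- uv_rulesets(c("spa_hla_b27", "fuchs_uveitis", "synthetic_viral_au"))
  f <- recode(generate_cohort(cohort_spec(rs3, n_cases = 240, seed = 4)))
  lmax <- lambda_max(f$x, f$labels)
  lambdas <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = 10))
  nz <- vapply(lambdas, function(l) {
    m <- fit_multinomial_lasso(f$x, f$labels, lambda = l)
    sum(rowSums(abs(m$beta)) > 0)
  }, 0L)
  expect_true(all(diff(nz) >= 0))  # decreasing lambda never drops features
  expect_identical(nz[1], 0L)
})

test_that("predict: probabilities sum to one, ties break by class order, columns must match", {
  d <- sep_data()
  m <- fit_multinomial_lasso(d$x, d$y, lambda = 0.01)
  pr <- predict(m, d$x)$prob
  expect_true(all(abs(rowSums(pr) - 1) < 1e-12))
  expect_true(all(pr > 0))
  m0 <- m
  m0$beta[] <- 0
  m0$intercepts[] <- 0                      # exact tie
  expect_true(all(predict(m0, d$x)$label == m0$classes[1]))
  bad <- d$x
  colnames(bad) <- c("a", "b", "c")
  expect_error(predict(m, bad), "feature")
})

test_that("cv with the one-standard-error rule runs end to end and is seeded", {
  rs3 <- uv_rulesets(c("spa_hla_b27", "fuchs_uveitis", "synthetic_viral_au"))
  f <- recode(generate_cohort(cohort_spec(rs3, n_cases = 150, seed = 12)))
  m1 <- fit_multinomial_lasso(f$x, f$labels, lambda = "cv", seed = 3)
  m2 <- fit_multinomial_lasso(f$x, f$labels, lambda = "cv", seed = 3)
  expect_identical(m1$lambda, m2$lambda)
  expect_identical(m1$beta, m2$beta)
  expect_gt(m1$lambda, 0)
})

test_that("models round-trip through JSON", {
  d <- sep_data()
  m <- fit_multinomial_lasso(d$x, d$y, lambda = 0.01)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(m2$beta, m$beta, tolerance = 1e-12)
  expect_equal(unname(m2$intercepts), unname(m$intercepts), tolerance = 1e-12)
  expect_identical(m2$classes, m$classes)
  expect_identical(
    as.character(predict(m2, d$x)$label),
    as.character(predict(m, d$x)$label))
})
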