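# Synthetic labeled cohorts ----------------------------------------------------
#
# The real multi-disease case database behind the published criteria is not
# public, so the derivation pipeline is exercised on synthetic cohorts: each
# case is constructed as a satisfying assignment of its disease's criteria
# tree (uniform choice among OR branches, transactional backtracking on
# conflicts), with that disease's exclusion triggers forced negative,
# unreferenced vocabulary fields drawn from background frequencies, and
# flip/missingness noise applied afterwards.

# --- constraint store ---------------------------------------------------------

new_store <- function() {
  list(findings = list(),      # code -> list(value, grade)
       tests = list(),         # code -> "positive"/"negative"/"unknown"
       course = NULL,          # allowed set or NULL (unconstrained)
       laterality = NULL)
}

store_set_finding <- function(store, code, value, grade = NULL) {
  cur <- store$findings[[code]]
  if (!is.null(cur)) {
    if (cur$value != value) return(NULL)
    if (!is.null(grade) && !is.null(cur$grade) && cur$grade != grade) return(NULL)
    if (is.null(grade)) grade <- cur$grade
  }
  store$findings[[code]] <- list(value = value, grade = grade)
  store
}

store_set_test <- function(store, code, value) {
  cur <- store$tests[[code]]
  if (!is.null(cur) && cur != value) return(NULL)
  store$tests[[code]] <- value
  store
}

store_restrict <- function(store, field, allowed) {
  cur <- store[[field]]
  allowed <- if (is.null(cur)) allowed else intersect(cur, allowed)
  if (!length(allowed)) return(NULL)
  store[[field]] <- allowed
  store
}

# --- satisfying / falsifying assignment --------------------------------------

# Returns an updated store, or NULL when the branch cannot be satisfied.
satisfy <- function(expr, store, positive = TRUE) {
  kind <- expr$kind
  if (kind == "true") return(if (positive) store else NULL)
  if (kind == "not") return(satisfy(expr$child, store, !positive))
  if (kind %in% c("and", "or")) {
    all_of <- (kind == "and") == positive
    if (all_of) {            # satisfy AND / falsify OR: every child
      for (child in expr$children) {
        store <- satisfy(child, store, positive)
        if (is.null(store)) return(NULL)
      }
      return(store)
    }
    # satisfy OR / falsify AND: one child, uniform first choice with backtracking
    for (child in expr$children[sample.int(length(expr$children))]) {
      attempt <- satisfy(child, store, positive)
      if (!is.null(attempt)) return(attempt)
    }
    return(NULL)
  }
  satisfy_leaf(expr, store, positive)
}

satisfy_leaf <- function(expr, store, positive) {
  switch(expr$kind,
    "finding_is" = {
      if (positive) store_set_finding(store, expr$code, expr$value)
      else if (expr$value == "present") store_set_finding(store, expr$code, "absent")
      else if (expr$value == "absent") store_set_finding(store, expr$code, "present")
      else {  # falsify "unknown": any recorded state; prefer absent
        store_set_finding(store, expr$code, "absent") %||%
          store_set_finding(store, expr$code, "present")
      }
    },
    "test_is" = {
      if (positive) store_set_test(store, expr$code, expr$value)
      else if (expr$value == "positive") store_set_test(store, expr$code, "negative")
      else if (expr$value == "negative") store_set_test(store, expr$code, "positive")
      else store_set_test(store, expr$code, "negative") %||%
           store_set_test(store, expr$code, "positive")
    },
    "course_in" = {
      allowed <- if (positive) expr$values
                 else setdiff(setdiff(uv_courses(), "unknown"), expr$values)
      if (!length(allowed)) NULL else store_restrict(store, "course", allowed)
    },
    "laterality_in" = {
      allowed <- if (positive) expr$values
                 else setdiff(setdiff(uv_lateralities(), "unknown"), expr$values)
      if (!length(allowed)) NULL else store_restrict(store, "laterality", allowed)
    },
    "grade_lt" = {
      if (positive) {
        pairs <- which(outer(1:4, 1:4, `<`), arr.ind = TRUE)
        for (k in sample.int(nrow(pairs))) {
          attempt <- store_set_finding(store, expr$code, "present", pairs[k, 1])
          if (is.null(attempt)) next
          attempt <- store_set_finding(attempt, expr$than, "present", pairs[k, 2])
          if (!is.null(attempt)) return(attempt)
        }
        NULL
      } else {
        # definite false needs both grades known with grade(code) >= grade(than);
        # absent counts as grade 0
        states <- c(list(list(value = "absent", grade = 0L)),
                    lapply(1:4, function(g) list(value = "present", grade = g)))
        combos <- expand.grid(a = seq_along(states), b = seq_along(states))
        combos <- combos[vapply(seq_len(nrow(combos)), function(k) {
          states[[combos$a[k]]]$grade >= states[[combos$b[k]]]$grade
        }, TRUE), , drop = FALSE]
        for (k in sample.int(nrow(combos))) {
          sa <- states[[combos$a[k]]]; sb <- states[[combos$b[k]]]
          a <- store_set_finding(store, expr$code, sa$value,
                                 if (sa$value == "present") sa$grade)
          if (is.null(a)) next
          a <- store_set_finding(a, expr$than, sb$value,
                                 if (sb$value == "present") sb$grade)
          if (!is.null(a)) return(a)
        }
        NULL
      }
    },
    "grade_ge" = {
      if (positive) {
        for (g in sample(expr$grade:4)) {
          attempt <- store_set_finding(store, expr$code, "present", g)
          if (!is.null(attempt)) return(attempt)
        }
        NULL
      } else {
        attempt <- store_set_finding(store, expr$code, "absent")
        if (!is.null(attempt)) return(attempt)
        if (expr$grade > 1L) {
          for (g in sample.int(expr$grade - 1L)) {
            attempt <- store_set_finding(store, expr$code, "present", g)
            if (!is.null(attempt)) return(attempt)
          }
        }
        NULL
      }
    }
  )
}

# Positive-polarity finding/test leaves of an expression (the fields whose
# definite values can trigger it).
trigger_leaves <- function(expr, positive = TRUE) {
  switch(expr$kind,
    "and" = , "or" = do.call(rbind, lapply(expr$children, trigger_leaves, positive = positive)),
    "not" = trigger_leaves(expr$child, !positive),
    "finding_is" = , "test_is" = if (positive)
      data.frame(kind = expr$kind, code = expr$code, value = expr$value,
                 stringsAsFactors = FALSE),
    NULL
  )
}

#' Sample one case satisfying a rule set
#'
#' Constructs a satisfying assignment of the criteria tree (OR branches
#' chosen uniformly, with backtracking), forces the rule set's own
#' exclusion-trigger fields negative, samples every other vocabulary field
#' from background frequencies (`background_rate` present/positive, default
#' 5\%), and leaves course/laterality that the criteria do not constrain as
#' `unknown`.  Pre-noise, the returned case always classifies into the rule
#' set.  Uses the current R RNG state.
#'
#' @param rs A [rule_set()].
#' @param case_id Identifier for the new case.
#' @param background_rate Present/positive probability for unreferenced
#'   fields; may be a single number or a named vector keyed by code with a
#'   `".default"` entry.
#' @return A [uv_case()] with `true_label = rs$disease_id`.
#' @export
sample_case <- function(rs, case_id = "synthetic", background_rate = 0.05) {
  store <- satisfy(rs$criteria, new_store(), positive = TRUE)
  if (is.null(store))
    stop("rule set '", rs$disease_id, "' has unsatisfiable criteria", call. = FALSE)
  # falsify this disease's own exclusion triggers (only unconstrained fields)
  for (ex in rs$exclusions) {
    leaves <- trigger_leaves(ex)
    for (i in seq_len(NROW(leaves))) {
      code <- leaves$code[i]
      if (leaves$kind[i] == "finding_is" && is.null(store$findings[[code]]) &&
          leaves$value[i] == "present")
        store <- store_set_finding(store, code, "absent")
      else if (leaves$kind[i] == "test_is" && is.null(store$tests[[code]]) &&
               leaves$value[i] == "positive")
        store <- store_set_test(store, code, "negative")
    }
  }
  bg <- function(code) {
    if (length(background_rate) == 1L && is.null(names(background_rate)))
      return(background_rate)
    unname(background_rate[code] %|na|% background_rate[".default"] %|na|% 0.05)
  }
  findings <- list()
  for (code in uv_finding_codes()) {
    f <- store$findings[[code]]
    if (is.null(f)) {
      value <- if (stats::runif(1) < bg(code)) "present" else "absent"
      f <- list(value = value, grade = NULL)
    }
    if (f$value == "unknown") next
    if (f$value == "present" && uv_is_gradable(code) && is.null(f$grade))
      f$grade <- sample.int(4L, 1L)
    findings[[code]] <- f
  }
  tests <- list()
  for (code in uv_test_codes()) {
    t <- store$tests[[code]]
    if (is.null(t)) t <- if (stats::runif(1) < bg(code)) "positive" else "negative"
    if (t == "unknown") next
    tests[[code]] <- t
  }
  course <- if (is.null(store$course)) "unknown"
            else store$course[sample.int(length(store$course), 1L)]
  laterality <- if (is.null(store$laterality)) "unknown"
                else store$laterality[sample.int(length(store$laterality), 1L)]
  uv_case(case_id, anatomic_class = rs$anatomic_class, course = course,
          laterality = laterality, findings = findings, tests = tests,
          true_label = rs$disease_id)
}

`%|na|%` <- function(a, b) if (length(a) != 1L || is.na(a)) b else a

#' Specification of a synthetic cohort
#'
#' @param rulesets Named list of [rule_set()] objects (the diseases).
#' @param weights Prevalence weights (positive, recycled to the diseases);
#'   default equal.
#' @param n_cases Number of cases to generate.
#' @param flip_noise Probability that a recorded tri-state field is flipped
#'   (present<->absent, positive<->negative) after construction.
#' @param missing_rate Probability that a field is then set unknown.
#' @param train_fraction Proportion assigned to the training split,
#'   stratified by disease (strictly between 0 and 1).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param background_rate Passed to [sample_case()].
#' @return An object of class `uv_cohort_spec`.
#' @export
cohort_spec <- function(rulesets, n_cases, weights = NULL, flip_noise = 0,
                        missing_rate = 0, train_fraction = 2 / 3, seed = 1L,
                        background_rate = 0.05) {
  if (inherits(rulesets, "uv_ruleset")) rulesets <- list(rulesets)
  if (is.null(weights)) weights <- rep(1, length(rulesets))
  stopifnot(length(rulesets) >= 1L,
            all(is.finite(weights)), all(weights > 0),
            length(weights) == length(rulesets),
            n_cases >= 0,
            flip_noise >= 0, flip_noise <= 1,
            missing_rate >= 0, missing_rate <= 1)
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must be strictly between 0 and 1", call. = FALSE)
  structure(list(rulesets = rulesets, weights = weights,
                 n_cases = as.integer(n_cases), flip_noise = flip_noise,
                 missing_rate = missing_rate, train_fraction = train_fraction,
                 seed = as.integer(seed), background_rate = background_rate),
            class = "uv_cohort_spec")
}

apply_noise <- function(case, flip_noise, missing_rate) {
  flip_tri <- function(v, opp) if (stats::runif(1) < flip_noise) opp[v] else v
  f_opp <- c(present = "absent", absent = "present")
  t_opp <- c(positive = "negative", negative = "positive")
  if (flip_noise > 0) {
    for (code in names(case$findings)) {
      f <- case$findings[[code]]
      nv <- flip_tri(f$value, f_opp)
      if (nv != f$value) case$findings[[code]] <- list(value = unname(nv), grade = NULL)
    }
    for (code in names(case$tests))
      case$tests[[code]] <- unname(flip_tri(case$tests[[code]], t_opp))
  }
  if (missing_rate > 0) {
    keep <- stats::runif(length(case$findings)) >= missing_rate
    case$findings <- case$findings[keep]
    keep <- stats::runif(length(case$tests)) >= missing_rate
    case$tests <- case$tests[keep]
  }
  case
}

#' Generate a labeled synthetic cohort
#'
#' Deterministic given `spec$seed`: cases are sampled per [sample_case()],
#' flip noise and missingness are applied to findings and tests (never to
#' `case_id`/`true_label`, and exclusion-trigger fields participate so that
#' excluded verdicts occur in noisy cohorts), and a train/validation split
#' is drawn stratified by disease at `train_fraction`.
#'
#' @param spec A [cohort_spec()].
#' @return A [uv_cohort()] with `true_label` set on every case and a split.
#' @export
#' @examples
#' spec <- cohort_spec(uv_rulesets(), n_cases = 6, seed = 42)
#' generate_cohort(spec)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "uv_cohort_spec"))
  set.seed(spec$seed)
  ids <- vapply(spec$rulesets, `[[`, "", "disease_id")
  if (spec$n_cases == 0L) return(uv_cohort(list()))
  which_disease <- sample.int(length(ids), spec$n_cases, replace = TRUE,
                              prob = spec$weights)
  cases <- vector("list", spec$n_cases)
  for (i in seq_len(spec$n_cases)) {
    cs <- sample_case(spec$rulesets[[which_disease[i]]],
                      case_id = sprintf("case_%05d", i),
                      background_rate = spec$background_rate)
    cases[[i]] <- apply_noise(cs, spec$flip_noise, spec$missing_rate)
  }
  split <- rep("validation", spec$n_cases)
  for (d in seq_along(ids)) {
    idx <- which(which_disease == d)
    n_train <- round(spec$train_fraction * length(idx))
    if (length(idx)) split[sample(idx, n_train)] <- "train"
  }
  uv_cohort(cases, stats::setNames(split, vapply(cases, `[[`, "", "case_id")))
}
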