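# Model-to-rule distillation ---------------------------------------------------
#
# Phase III: the fitted multinomial lasso is a black box; a human-usable
# rule system is derived from it by fitting an unpruned decision-tree
# student on the model's own predictions (teacher labels), converting each
# class's leaves into a disjunctive normal form, and simplifying by
# absorption/subsumption without changing any decision on the cohort.
# Because the teacher label is a deterministic function of the features,
# growing the tree until leaves are pure guarantees 100% agreement on every
# case the tree was grown on; the contract is: agreement 1.0 or an explicit
# disagreement list, never a silent approximation.

# --- deterministic CART to purity --------------------------------------------

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

grow_student <- function(x, y, rows) {
  counts <- tabulate(y[rows], nbins = nlevels(y))
  if (max(counts) == sum(counts)) {
    return(list(leaf = TRUE, class = levels(y)[which.max(counts)]))
  }
  parent <- gini_impurity(counts)
  best <- NULL
  best_imp <- parent
  fallback <- NULL
  for (j in seq_len(ncol(x))) {
    left <- rows[x[rows, j] == 0L]
    if (length(left) == 0L || length(left) == length(rows)) next
    right <- rows[x[rows, j] == 1L]
    if (is.null(fallback)) fallback <- j
    imp <- (length(left) * gini_impurity(tabulate(y[left], nbins = nlevels(y))) +
            length(right) * gini_impurity(tabulate(y[right], nbins = nlevels(y)))) /
           length(rows)
    if (imp < best_imp - 1e-12) {   # strict improvement; ties keep lowest j
      best_imp <- imp
      best <- j
    }
  }
  if (is.null(best)) best <- fallback
  if (is.null(best)) {
    # impure but indistinguishable rows: deterministic teacher labels make
    # this unreachable; majority leaf keeps the function total anyway
    return(list(leaf = TRUE, class = levels(y)[which.max(counts)]))
  }
  list(leaf = FALSE, feature = colnames(x)[best],
       left = grow_student(x, y, rows[x[rows, best] == 0L]),
       right = grow_student(x, y, rows[x[rows, best] == 1L]))
}

# --- DNF handling ------------------------------------------------------------

# A term is a named integer vector (feature column -> required 0/1);
# a DNF is a list of terms; the empty term is TRUE.
tree_to_dnf <- function(node, classes) {
  dnf <- stats::setNames(vector("list", length(classes)), classes)
  walk <- function(nd, term) {
    if (nd$leaf) {
      dnf[[nd$class]][[length(dnf[[nd$class]]) + 1L]] <<- term
    } else {
      walk(nd$left, c(term, stats::setNames(0L, nd$feature)))
      walk(nd$right, c(term, stats::setNames(1L, nd$feature)))
    }
  }
  walk(node, stats::setNames(integer(0), character(0)))
  dnf
}

term_subsumes <- function(a, b) {
  # a subsumes b iff a's literals are a subset of b's (absorption drops b)
  all(names(a) %in% names(b)) && all(b[names(a)] == a)
}

simplify_dnf <- function(terms) {
  if (!length(terms)) return(terms)
  keep <- rep(TRUE, length(terms))
  for (i in seq_along(terms)) {
    if (!keep[i]) next
    for (j in seq_along(terms)) {
      if (i == j || !keep[j]) next
      if (term_subsumes(terms[[i]], terms[[j]])) keep[j] <- FALSE
    }
  }
  terms[keep]
}

dnf_complexity <- function(terms) sum(lengths(terms))

eval_dnf_row <- function(terms, row) {
  for (term in terms) {
    if (!length(term) || all(row[names(term)] == term)) return(TRUE)
  }
  FALSE
}

# Decision of a per-class DNF system on one feature row: first class (in
# class order) whose DNF fires; NA if none does.
dnf_decide <- function(dnf, row, classes) {
  for (cl in classes) if (eval_dnf_row(dnf[[cl]], row)) return(cl)
  NA_character_
}

# --- feature-column predicates ------------------------------------------------

# Map a recoded feature column name back to a rule-DSL predicate.
column_predicate <- function(col) {
  if (grepl(">=", col, fixed = TRUE)) {
    parts <- strsplit(col, ">=", fixed = TRUE)[[1]]
    return(grade_ge(parts[1], as.integer(parts[2])))
  }
  parts <- strsplit(col, "=", fixed = TRUE)[[1]]
  field <- parts[1]; value <- parts[2]
  if (field == "course") return(course_in(value))
  if (field == "laterality") return(laterality_in(value))
  kind <- uv_code_kind(field)
  if (is.na(kind)) stop("cannot map feature column '", col, "' to a predicate",
                        call. = FALSE)
  if (kind == "finding") finding_is(field, value) else test_is(field, value)
}

dnf_to_expr <- function(terms) {
  if (!length(terms)) return(rx_not(rx_true()))
  term_expr <- function(term) {
    if (!length(term)) return(rx_true())
    lits <- lapply(seq_along(term), function(i) {
      pred <- column_predicate(names(term)[i])
      if (term[[i]] == 1L) pred else rx_not(pred)
    })
    if (length(lits) == 1L) lits[[1]] else do.call(rx_and, lits)
  }
  exprs <- lapply(terms, term_expr)
  if (length(exprs) == 1L) exprs[[1]] else do.call(rx_or, exprs)
}

# Evaluate a (distilled) rule expression two-valued on a recoded feature row.
eval_expr_row <- function(expr, row) {
  switch(expr$kind,
    "true" = TRUE,
    "and" = all(vapply(expr$children, eval_expr_row, TRUE, row = row)),
    "or" = any(vapply(expr$children, eval_expr_row, TRUE, row = row)),
    "not" = !eval_expr_row(expr$child, row),
    "finding_is" = ,
    "test_is" = {
      col <- paste0(expr$code, "=", expr$value)
      if (expr$value %in% c("absent", "negative")) {
        pos <- if (expr$kind == "finding_is") "present" else "positive"
        row[paste0(expr$code, "=", pos)] == 0L &&
          row[paste0(expr$code, "=unknown")] == 0L
      } else row[col] == 1L
    },
    "course_in" = any(row[paste0("course=", expr$values)] == 1L),
    "laterality_in" = any(row[paste0("laterality=", expr$values)] == 1L),
    "grade_ge" = row[paste0(expr$code, ">=", expr$grade)] == 1L,
    stop("cannot evaluate '", expr$kind, "' on a recoded row", call. = FALSE)
  )
}

rules_decide <- function(rules, row, classes) {
  for (cl in classes) if (eval_expr_row(rules[[cl]], row)) return(cl)
  NA_character_
}

# --- public operations --------------------------------------------------------

#' Distill a fitted model into a logical rule system
#'
#' @param model A `uv_model` (see [fit_multinomial_lasso()]).
#' @param features A `uv_features` object ([recode()]) covering train and
#'   validation cases; the student is fit on the model's predictions for
#'   all of them, restricted to `model$selected_features` (an all-zero
#'   model yields a constant rule).
#' @return An object of class `uv_distillation`: `rules` (named list of
#'   `uv_expr`, one per class, exclusions out of scope), `dnf` (internal
#'   term lists), `agreement` (named proportions: `train`, `validation`,
#'   `overall`), `disagreements` (case ids), `complexity` (atom count per
#'   class rule) and `classes`.
#' @export
distill <- function(model, features) {
  x <- features$x
  if (!all(model$feature_names %in% colnames(x)))
    stop("feature matrix lacks columns required by the model", call. = FALSE)
  teacher <- predict(model, x[, model$feature_names, drop = FALSE])$label
  student_cols <- model$selected_features
  if (length(student_cols)) {
    xs <- x[, student_cols, drop = FALSE]
    tree <- grow_student(xs, teacher, seq_len(nrow(xs)))
  } else {
    xs <- x[, 0, drop = FALSE]
    tree <- list(leaf = TRUE, class = levels(teacher)[which.max(tabulate(teacher))])
  }
  dnf <- tree_to_dnf(tree, model$classes)
  raw_complexity <- vapply(dnf, dnf_complexity, 0L)
  simp <- lapply(dnf, simplify_dnf)
  # simplification soundness: decisions must be unchanged case by case
  for (i in seq_len(nrow(x))) {
    if (!identical(dnf_decide(dnf, x[i, ], model$classes),
                   dnf_decide(simp, x[i, ], model$classes)))
      stop("internal error: DNF simplification changed a decision",
           call. = FALSE)
  }
  decision <- vapply(seq_len(nrow(x)), function(i)
    dnf_decide(simp, x[i, ], model$classes), "")
  agree <- decision == as.character(teacher)
  agreement <- c(overall = mean(agree))
  if (!is.null(features$split)) {
    for (s in c("train", "validation")) {
      idx <- features$split == s
      agreement[[s]] <- if (any(idx)) mean(agree[idx]) else NA_real_
    }
  }
  structure(list(rules = lapply(simp, dnf_to_expr), dnf = simp,
                 agreement = agreement,
                 disagreements = features$case_ids[!agree],
                 complexity = vapply(simp, dnf_complexity, 0L),
                 raw_complexity = raw_complexity,
                 classes = model$classes),
            class = "uv_distillation")
}

#' @export
print.uv_distillation <- function(x, ...) {
  cat("<uv_distillation>", length(x$classes), "class rules; agreement:",
      paste(names(x$agreement), signif(x$agreement, 4), sep = "=", collapse = " "),
      "\n")
  for (cl in x$classes)
    cat("  ", cl, " (", x$complexity[[cl]], " atoms): ",
        format(x$rules[[cl]]), "\n", sep = "")
  invisible(x)
}

#' Agreement of a rule system with a model's decisions
#'
#' Mechanized counterpart of the published masked-reader audit: exact
#' agreement statistics between per-class rules and the model argmax, with
#' an optional random subsample (`sample_fraction = 0.1` mimics a 10\%
#' audit; sampling uses the current RNG state).
#'
#' @param rules Named list of `uv_expr`, one per model class.
#' @param model A `uv_model`.
#' @param features A `uv_features` object.
#' @param sample_fraction Fraction of cases to audit (default 1.0).
#' @return List with `n` (cases audited), `agreement` (per split and
#'   overall) and `disagreements` (case ids).
#' @export
check_agreement <- function(rules, model, features, sample_fraction = 1.0) {
  stopifnot(sample_fraction > 0, sample_fraction <= 1)
  x <- features$x
  idx <- seq_len(nrow(x))
  if (sample_fraction < 1) idx <- sort(sample(idx, round(sample_fraction * nrow(x))))
  teacher <- predict(model, x[idx, model$feature_names, drop = FALSE])$label
  decision <- vapply(idx, function(i) rules_decide(rules, x[i, ], model$classes), "")
  agree <- !is.na(decision) & decision == as.character(teacher)
  agreement <- c(overall = mean(agree))
  if (!is.null(features$split)) {
    sp <- features$split[idx]
    for (s in c("train", "validation")) {
      sel <- sp == s
      agreement[[s]] <- if (any(sel)) mean(agree[sel]) else NA_real_
    }
  }
  list(n = length(idx), agreement = agreement,
       disagreements = features$case_ids[idx][!agree])
}
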