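# Rule expressions and three-valued evaluation -------------------------------
#
# Criteria are boolean expression trees over predicates on a case record,
# evaluated under strong Kleene three-valued logic: AND = min, OR = max over
# the ordering F < U < T, NOT swaps T/F and fixes U.  A predicate over an
# unassessed ("unknown") field yields U, so an incomplete workup never
# classifies and never excludes -- it propagates as indeterminate.

KLEENE <- c("F", "U", "T")

k_and <- function(vals) {
  if (any(vals == "F")) "F" else if (any(vals == "U")) "U" else "T"
}

k_or <- function(vals) {
  if (any(vals == "T")) "T" else if (any(vals == "U")) "U" else "F"
}

k_not <- function(val) switch(val, "T" = "F", "F" = "T", "U")

k_bool <- function(b) if (isTRUE(b)) "T" else "F"

# Constructors ----------------------------------------------------------------

new_expr <- function(x) structure(x, class = "uv_expr")

#' Predicate and connective constructors for rule expressions
#'
#' Rule expressions are finite trees whose leaves are predicates over a case
#' record and whose internal nodes are `and`/`or`/`not` connectives.
#' Predicates over a tri-state field evaluate to unknown (`"U"`) when the
#' field is unassessed, with one deliberate exception: asking for the value
#' `"unknown"` itself (or including `"unknown"` in a `course_in`/
#' `laterality_in` set) is a two-valued question about the *recorded* state,
#' used by distilled rules that treat missingness as its own indicator.
#'
#' @param code,than Vocabulary codes.
#' @param value Expected tri-state value.
#' @param values Set of course/laterality values.
#' @param grade Ordinal severity threshold (1--4).
#' @param ... Child expressions.
#' @param x A child expression.
#' @return A `uv_expr` tree node.
#' @name rule-expressions
NULL

#' @rdname rule-expressions
#' @export
finding_is <- function(code, value = "present") {
  stopifnot(value %in% FINDING_STATES)
  new_expr(list(kind = "finding_is", code = code, value = value))
}

#' @rdname rule-expressions
#' @export
test_is <- function(code, value = "positive") {
  stopifnot(value %in% TEST_STATES)
  new_expr(list(kind = "test_is", code = code, value = value))
}

#' @rdname rule-expressions
#' @export
course_in <- function(values) {
  stopifnot(all(values %in% uv_courses()))
  new_expr(list(kind = "course_in", values = as.character(values)))
}

#' @rdname rule-expressions
#' @export
laterality_in <- function(values) {
  stopifnot(all(values %in% uv_lateralities()))
  new_expr(list(kind = "laterality_in", values = as.character(values)))
}

#' @rdname rule-expressions
#' @export
grade_lt <- function(code, than) {
  new_expr(list(kind = "grade_lt", code = code, than = than))
}

#' @rdname rule-expressions
#' @export
grade_ge <- function(code, grade) {
  stopifnot(grade %in% 1:4)
  new_expr(list(kind = "grade_ge", code = code, grade = as.integer(grade)))
}

#' @rdname rule-expressions
#' @export
rx_and <- function(...) new_expr(list(kind = "and", children = list(...)))

#' @rdname rule-expressions
#' @export
rx_or <- function(...) new_expr(list(kind = "or", children = list(...)))

#' @rdname rule-expressions
#' @export
rx_not <- function(x) new_expr(list(kind = "not", child = x))

#' @rdname rule-expressions
#' @export
rx_true <- function() new_expr(list(kind = "true"))

is_connective <- function(expr) expr$kind %in% c("and", "or", "not", "true")

# Evaluation -------------------------------------------------------------------

#' Evaluate a rule expression on a case under Kleene logic
#'
#' @param expr A `uv_expr`.
#' @param case A `uv_case`.
#' @return `"T"`, `"F"` or `"U"`.
#' @export
#' @examples
#' cs <- uv_case("x", findings = list(heterochromia = "present"))
#' eval_expr(rx_or(finding_is("heterochromia"), finding_is("endotheliitis")), cs)
eval_expr <- function(expr, case) {
  switch(expr$kind,
    "true" = "T",
    "and" = k_and(vapply(expr$children, eval_expr, "", case = case)),
    "or" = k_or(vapply(expr$children, eval_expr, "", case = case)),
    "not" = k_not(eval_expr(expr$child, case)),
    "finding_is" = ,
    "test_is" = {
      actual <- case_value(case, expr$code)
      if (expr$value == "unknown") k_bool(actual == "unknown")
      else if (actual == "unknown") "U"
      else k_bool(actual == expr$value)
    },
    "course_in" = {
      if ("unknown" %in% expr$values) k_bool(case$course %in% expr$values)
      else if (case$course == "unknown") "U"
      else k_bool(case$course %in% expr$values)
    },
    "laterality_in" = {
      if ("unknown" %in% expr$values) k_bool(case$laterality %in% expr$values)
      else if (case$laterality == "unknown") "U"
      else k_bool(case$laterality %in% expr$values)
    },
    "grade_lt" = {
      a <- case_grade(case, expr$code)
      b <- case_grade(case, expr$than)
      if (is.na(a) || is.na(b)) "U" else k_bool(a < b)
    },
    "grade_ge" = {
      g <- case_grade(case, expr$code)
      if (is.na(g)) "U" else k_bool(g >= expr$grade)
    },
    stop("unknown expression kind: ", expr$kind, call. = FALSE)
  )
}

# Atom inventory ---------------------------------------------------------------

#' Enumerate the atomic fields referenced by an expression
#'
#' @param expr A `uv_expr`.
#' @return A named list of atom descriptors (`kind`, `code`, `graded`); the
#'   names are stable keys (`finding:<code>`, `test:<code>`, `course`,
#'   `laterality`).
#' @export
expr_atoms <- function(expr) {
  atoms <- list()
  walk <- function(e) {
    switch(e$kind,
      "and" = , "or" = lapply(e$children, walk),
      "not" = walk(e$child),
      "true" = NULL,
      "finding_is" = {
        key <- paste0("finding:", e$code)
        prev <- atoms[[key]]
        atoms[[key]] <<- list(kind = "finding", code = e$code,
                              graded = isTRUE(prev$graded))
      },
      "test_is" = {
        atoms[[paste0("test:", e$code)]] <<- list(kind = "test", code = e$code,
                                                  graded = FALSE)
      },
      "course_in" = { atoms[["course"]] <<- list(kind = "course", graded = FALSE) },
      "laterality_in" = { atoms[["laterality"]] <<- list(kind = "laterality", graded = FALSE) },
      "grade_lt" = {
        for (code in c(e$code, e$than))
          atoms[[paste0("finding:", code)]] <<- list(kind = "finding", code = code,
                                                     graded = TRUE)
      },
      "grade_ge" = {
        atoms[[paste0("finding:", e$code)]] <<- list(kind = "finding", code = e$code,
                                                     graded = TRUE)
      }
    )
    invisible(NULL)
  }
  walk(expr)
  atoms
}

# Validation -------------------------------------------------------------------

#' Validate an expression against the vocabulary registry
#'
#' @param expr A `uv_expr`.
#' @return Invisibly `TRUE`; errors on the first violation (unregistered
#'   code, wrong code kind, grade predicate over a non-gradable finding).
#' @export
validate_expr <- function(expr) {
  walk <- function(e, path) {
    check_code <- function(code, kind) {
      k <- uv_code_kind(code)
      if (is.na(k)) stop("at ", path, ": code '", code,
                         "' is not in the vocabulary registry", call. = FALSE)
      if (k != kind) stop("at ", path, ": code '", code, "' is a ", k,
                          ", not a ", kind, call. = FALSE)
    }
    switch(e$kind,
      "and" = , "or" = {
        if (!length(e$children)) stop("at ", path, ": empty ", e$kind, call. = FALSE)
        for (i in seq_along(e$children))
          walk(e$children[[i]], paste0(path, "/", e$kind, "[", i, "]"))
      },
      "not" = walk(e$child, paste0(path, "/not")),
      "true" = NULL,
      "finding_is" = check_code(e$code, "finding"),
      "test_is" = check_code(e$code, "test"),
      "course_in" = , "laterality_in" = NULL,
      "grade_lt" = {
        for (code in c(e$code, e$than)) {
          check_code(code, "finding")
          if (!uv_is_gradable(code))
            stop("at ", path, ": grade comparison over non-gradable finding '",
                 code, "'", call. = FALSE)
        }
      },
      "grade_ge" = {
        check_code(e$code, "finding")
        if (!uv_is_gradable(e$code))
          stop("at ", path, ": grade threshold over non-gradable finding '",
               e$code, "'", call. = FALSE)
      },
      stop("at ", path, ": unknown node kind '", e$kind, "'", call. = FALSE)
    )
    invisible(TRUE)
  }
  walk(expr, "$")
  invisible(TRUE)
}

# Pretty-printing --------------------------------------------------------------

#' @export
format.uv_expr <- function(x, ...) {
  switch(x$kind,
    "true" = "TRUE",
    "and" = paste0("(", paste(vapply(x$children, format, ""), collapse = " AND "), ")"),
    "or" = paste0("(", paste(vapply(x$children, format, ""), collapse = " OR "), ")"),
    "not" = paste0("NOT ", format(x$child)),
    "finding_is" = paste0(x$code, "=", x$value),
    "test_is" = paste0(x$code, "=", x$value),
    "course_in" = paste0("course∈{", paste(x$values, collapse = ","), "}"),
    "laterality_in" = paste0("laterality∈{", paste(x$values, collapse = ","), "}"),
    "grade_lt" = paste0("grade(", x$code, ") < grade(", x$than, ")"),
    "grade_ge" = paste0("grade(", x$code, ") >= ", x$grade)
  )
}

#' @export
print.uv_expr <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
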