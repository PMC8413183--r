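# Independent brute-force truth-table oracle for rule evaluation.
#
# The engine computes strong Kleene connectives as min/max over an ordering
# of F < U < T.  The oracle takes a different route to the same semantics:
# each leaf's three-valued value is computed by its own accessors, and
# connectives are combined through explicit lookup tables.  The
# engine-vs-oracle test enumerates every assignment of an expression's atom
# domain and compares the two evaluators value by value.

ORACLE_AND <- matrix(c("T", "U", "F",
                       "U", "U", "F",
                       "F", "F", "F"),
                     nrow = 3, byrow = TRUE,
                     dimnames = list(c("T", "U", "F"), c("T", "U", "F")))
ORACLE_OR <- matrix(c("T", "T", "T",
                      "T", "U", "U",
                      "T", "U", "F"),
                    nrow = 3, byrow = TRUE,
                    dimnames = list(c("T", "U", "F"), c("T", "U", "F")))
ORACLE_NOT <- c(T = "F", U = "U", F = "T")

oracle_finding <- function(case, code) {
  f <- case$findings[[code]]
  if (is.null(f)) "unknown" else f$value
}

oracle_grade <- function(case, code) {
  f <- case$findings[[code]]
  if (is.null(f) || f$value == "unknown") return(NA_integer_)
  if (f$value == "absent") return(0L)
  if (is.null(f$grade)) NA_integer_ else f$grade
}

oracle_test <- function(case, code) {
  t <- case$tests[[code]]
  if (is.null(t)) "unknown" else unname(t)
}

oracle_tri <- function(actual, expected) {
  # three-valued leaf verdict for a tri-state field
  if (expected == "unknown") return(if (actual == "unknown") "T" else "F")
  if (actual == "unknown") return("U")
  if (actual == expected) "T" else "F"
}

oracle_eval <- function(expr, case) {
  k <- expr$kind
  if (k == "true") return("T")
  if (k == "and") {
    out <- "T"
    for (child in expr$children) out <- ORACLE_AND[out, oracle_eval(child, case)]
    return(out)
  }
  if (k == "or") {
    out <- "F"
    for (child in expr$children) out <- ORACLE_OR[out, oracle_eval(child, case)]
    return(out)
  }
  if (k == "not") return(unname(ORACLE_NOT[oracle_eval(expr$child, case)]))
  if (k == "finding_is")
    return(oracle_tri(oracle_finding(case, expr$code), expr$value))
  if (k == "test_is")
    return(oracle_tri(oracle_test(case, expr$code), expr$value))
  if (k == "course_in") {
    if ("unknown" %in% expr$values)
      return(if (case$course %in% expr$values) "T" else "F")
    if (case$course == "unknown") return("U")
    return(if (case$course %in% expr$values) "T" else "F")
  }
  if (k == "laterality_in") {
    if ("unknown" %in% expr$values)
      return(if (case$laterality %in% expr$values) "T" else "F")
    if (case$laterality == "unknown") return("U")
    return(if (case$laterality %in% expr$values) "T" else "F")
  }
  if (k == "grade_lt") {
    a <- oracle_grade(case, expr$code); b <- oracle_grade(case, expr$than)
    if (is.na(a) || is.na(b)) return("U")
    return(if (a < b) "T" else "F")
  }
  if (k == "grade_ge") {
    g <- oracle_grade(case, expr$code)
    if (is.na(g)) return("U")
    return(if (g >= expr$grade) "T" else "F")
  }
  stop("oracle: unknown kind ", k)
}
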