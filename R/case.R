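# Case data model -----------------------------------------------------------

#' Construct a patient case record
#'
#' A case record holds the standardized description of one uveitis case:
#' demographic/anatomic descriptors, the clinical course, laterality, a set
#' of tri-state clinical findings (optionally graded 0--4) and a set of
#' tri-state laboratory/imaging test results.  Fields that were not assessed
#' are simply omitted; an omitted field and an explicit `"unknown"` are
#' equivalent, and the constructor canonicalizes to the omitted form so that
#' file round-trips are the identity.
#'
#' @param case_id Unique case identifier (non-empty string).
#' @param anatomic_class One of [uv_anatomic_classes()].
#' @param course One of `"acute"`, `"recurrent_acute"`, `"chronic"`,
#'   `"chronic_after_recurrent_acute"`, `"unknown"`.
#' @param laterality One of `"unilateral"`, `"alternating_unilateral"`,
#'   `"bilateral"`, `"unknown"`.
#' @param findings Named list; each element is `"present"`/`"absent"` or a
#'   list `list(value =, grade =)`; names are vocabulary finding codes.
#'   A grade of 0 is canonicalized to `absent` with no grade.
#' @param tests Named character vector or list of `"positive"`/`"negative"`
#'   values; names are vocabulary test codes.
#' @param true_label Optional disease identifier (consensus or synthetic
#'   ground-truth label).
#' @return An object of class `uv_case`.
#' @seealso [validate_case()], [read_cases()]
#' @export
#' @examples
#' uv_case("F1", "anterior", laterality = "unilateral",
#'         findings = list(anterior_chamber_cells = list(value = "present", grade = 1),
#'                         heterochromia = "present"),
#'         tests = list(hla_b27 = "negative"))
uv_case <- function(case_id, anatomic_class = "anterior", course = "unknown",
                    laterality = "unknown", findings = list(), tests = list(),
                    true_label = NULL) {
  fnd <- list()
  for (code in names(findings)) {
    f <- findings[[code]]
    if (!is.list(f)) f <- list(value = f, grade = NULL)
    value <- tolower(as.character(f$value))
    grade <- f$grade
    if (!is.null(grade) && !is.na(grade)) {
      grade <- as.integer(grade)
      if (grade == 0L) { value <- "absent"; grade <- NULL }
    } else grade <- NULL
    if (identical(value, "unknown")) next
    fnd[[code]] <- list(value = value, grade = grade)
  }
  tst <- list()
  for (code in names(tests)) {
    value <- tolower(as.character(tests[[code]]))
    if (identical(value, "unknown")) next
    tst[[code]] <- value
  }
  structure(list(case_id = as.character(case_id),
                 anatomic_class = as.character(anatomic_class),
                 course = tolower(as.character(course)),
                 laterality = tolower(as.character(laterality)),
                 findings = fnd, tests = tst,
                 true_label = if (is.null(true_label) || is.na(true_label) ||
                                  !nzchar(true_label)) NULL else as.character(true_label)),
            class = "uv_case")
}

#' Look up the tri-state value of a finding or test on a case
#'
#' @param case A `uv_case`.
#' @param code A vocabulary code.
#' @return For findings, `"present"`, `"absent"` or `"unknown"`; for tests,
#'   `"positive"`, `"negative"` or `"unknown"`.  Unrecorded fields are
#'   `"unknown"`.
#' @export
case_value <- function(case, code) {
  kind <- uv_code_kind(code)
  if (is.na(kind)) stop("unknown vocabulary code: ", code, call. = FALSE)
  if (kind == "finding") {
    f <- case$findings[[code]]
    if (is.null(f)) "unknown" else f$value
  } else {
    t <- case$tests[[code]]
    if (is.null(t) || is.na(t)) "unknown" else unname(t)
  }
}

# Severity grade of a gradable finding: integer 0-4 or NA when unknown.
# An absent finding has grade 0; a present finding without a recorded grade
# has an unknown (NA) grade.
case_grade <- function(case, code) {
  f <- case$findings[[code]]
  if (is.null(f)) return(NA_integer_)
  if (f$value == "absent") return(0L)
  if (f$value == "unknown") return(NA_integer_)
  if (is.null(f$grade)) NA_integer_ else f$grade
}

#' Validate a case record against the data-model invariants
#'
#' Violations are returned as data, not raised: an empty character vector
#' means the record satisfies every invariant (codes registered, tri-state
#' values well formed, grades only on gradable findings, grade/value
#' consistency, enum fields in range).
#'
#' @param case A `uv_case`.
#' @return Character vector of human-readable violations (empty if valid).
#' @export
validate_case <- function(case) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  if (!is.character(case$case_id) || length(case$case_id) != 1L || !nzchar(case$case_id))
    add("case_id: must be a non-empty string")
  if (!case$anatomic_class %in% uv_anatomic_classes())
    add(paste0("anatomic_class: '", case$anatomic_class, "' not one of the model strata"))
  if (!case$course %in% uv_courses())
    add(paste0("course: '", case$course, "' not a recognized course"))
  if (!case$laterality %in% uv_lateralities())
    add(paste0("laterality: '", case$laterality, "' not a recognized laterality"))
  fcodes <- uv_finding_codes()
  for (code in names(case$findings)) {
    f <- case$findings[[code]]
    if (!code %in% fcodes) {
      add(paste0("findings/", code, ": not a registered finding code"))
      next
    }
    if (!f$value %in% FINDING_STATES)
      add(paste0("findings/", code, ": value '", f$value, "' not in {present, absent, unknown}"))
    if (!is.null(f$grade)) {
      if (!uv_is_gradable(code))
        add(paste0("findings/", code, ": grade given but code is not gradable"))
      else if (f$grade < 0L || f$grade > 4L)
        add(paste0("findings/", code, ": grade must be in 0..4"))
      else if (f$grade > 0L && f$value != "present")
        add(paste0("findings/", code, ": grade > 0 requires value 'present'"))
      else if (f$grade == 0L && f$value == "present")
        add(paste0("findings/", code, ": grade 0 contradicts value 'present'"))
    }
  }
  tcodes <- uv_test_codes()
  for (code in names(case$tests)) {
    if (!code %in% tcodes) {
      add(paste0("tests/", code, ": not a registered test code"))
      next
    }
    if (!case$tests[[code]] %in% TEST_STATES)
      add(paste0("tests/", code, ": value '", case$tests[[code]],
                 "' not in {positive, negative, unknown}"))
  }
  v
}

#' @export
print.uv_case <- function(x, ...) {
  cat("<uv_case>", x$case_id, "-", x$anatomic_class,
      paste0("(", x$course, ", ", x$laterality, ")"),
      if (!is.null(x$true_label)) paste0("[", x$true_label, "]") else "", "\n")
  for (code in names(x$findings)) {
    f <- x$findings[[code]]
    cat("  finding ", code, ": ", f$value,
        if (!is.null(f$grade)) paste0(" (grade ", f$grade, ")") else "", "\n", sep = "")
  }
  for (code in names(x$tests)) cat("  test    ", code, ": ", x$tests[[code]], "\n", sep = "")
  invisible(x)
}

# Cohort ---------------------------------------------------------------------

#' Construct a cohort of case records
#'
#' @param cases List of `uv_case` objects.
#' @param split Optional named character vector mapping every `case_id` to
#'   `"train"` or `"validation"`; must cover each case exactly once.
#' @return An object of class `uv_cohort`.
#' @export
uv_cohort <- function(cases, split = NULL) {
  ids <- vapply(cases, function(cs) cs$case_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate case_id in cohort: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (!is.null(split)) {
    if (!setequal(names(split), ids) || length(split) != length(ids))
      stop("split must cover every case_id exactly once", call. = FALSE)
    if (!all(split %in% c("train", "validation")))
      stop("split values must be 'train' or 'validation'", call. = FALSE)
    split <- split[ids]  # align with case order
  }
  structure(list(cases = cases, split = split), class = "uv_cohort")
}

#' @export
length.uv_cohort <- function(x) length(x$cases)

#' @export
print.uv_cohort <- function(x, ...) {
  cat("<uv_cohort> of", length(x$cases), "cases")
  if (!is.null(x$split))
    cat(" (", sum(x$split == "train"), " train / ",
        sum(x$split == "validation"), " validation)", sep = "")
  cat("\n")
  labs <- cohort_labels(x)
  if (any(!is.na(labs))) print(table(labs, useNA = "ifany"))
  invisible(x)
}

cohort_ids <- function(cohort) {
  vapply(cohort$cases, function(cs) cs$case_id, character(1))
}

cohort_labels <- function(cohort) {
  vapply(cohort$cases, function(cs) {
    if (is.null(cs$true_label)) NA_character_ else cs$true_label
  }, character(1))
}

#' Validate every case of a cohort
#'
#' @param cohort A `uv_cohort`.
#' @return Named list (by case_id) of violation vectors; only offending cases
#'   appear.
#' @export
validate_cohort <- function(cohort) {
  out <- list()
  for (cs in cohort$cases) {
    v <- validate_case(cs)
    if (length(v)) out[[cs$case_id]] <- v
  }
  out
}

#' Restrict a cohort to a subset of cases
#'
#' @param cohort A `uv_cohort`.
#' @param idx Logical or integer index over cases.
#' @return A `uv_cohort` with the selected cases (split restricted alongside).
#' @export
cohort_subset <- function(cohort, idx) {
  cases <- cohort$cases[idx]
  split <- cohort$split
  if (!is.null(split)) split <- split[vapply(cases, `[[`, "", "case_id")]
  uv_cohort(cases, split)
}
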