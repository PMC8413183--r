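# Rule sets and the JSON rule DSL ---------------------------------------------
#
# A rule set is the machine-readable form of one disease's classification
# criteria: a single criteria expression tree plus an ordered list of
# exclusion expressions.  Exclusions dominate: a case for which any
# exclusion evaluates definitely true is excluded no matter what the
# criteria say.

#' Construct a disease rule set
#'
#' @param disease_id Unique identifier (e.g. `"fuchs_uveitis"`).
#' @param disease_name Human-readable name.
#' @param anatomic_class One of [uv_anatomic_classes()]; the model stratum
#'   the disease belongs to.
#' @param criteria A `uv_expr` (non-empty).
#' @param exclusions List of `uv_expr` (may be empty).
#' @param provenance Free-text citation for the rule content.
#' @return An object of class `uv_ruleset`.
#' @export
rule_set <- function(disease_id, disease_name, anatomic_class, criteria,
                     exclusions = list(), provenance = "") {
  stopifnot(anatomic_class %in% uv_anatomic_classes())
  validate_expr(criteria)
  for (ex in exclusions) validate_expr(ex)
  structure(list(disease_id = disease_id, disease_name = disease_name,
                 anatomic_class = anatomic_class, criteria = criteria,
                 exclusions = exclusions, provenance = provenance),
            class = "uv_ruleset")
}

#' @export
print.uv_ruleset <- function(x, ...) {
  cat("<uv_ruleset>", x$disease_id, "-", x$disease_name,
      paste0("[", x$anatomic_class, "]"), "\n")
  cat("criteria:  ", format(x$criteria), "\n")
  for (i in seq_along(x$exclusions))
    cat("exclusion ", i, ": ", format(x$exclusions[[i]]), "\n", sep = "")
  invisible(x)
}

# DSL parsing ------------------------------------------------------------------

expr_from_json <- function(node, path = "$") {
  if (!is.list(node))
    stop("rule DSL error at ", path, ": expected an object", call. = FALSE)
  keys <- setdiff(names(node), "comment")
  if (length(keys) != 1L)
    stop("rule DSL error at ", path,
         ": node must have exactly one operator key, got {",
         paste(keys, collapse = ", "), "}", call. = FALSE)
  key <- keys
  body <- node[[key]]
  switch(key,
    "and" = do.call(rx_and, lapply(seq_along(body), function(i)
      expr_from_json(body[[i]], paste0(path, ".and[", i, "]")))),
    "or" = do.call(rx_or, lapply(seq_along(body), function(i)
      expr_from_json(body[[i]], paste0(path, ".or[", i, "]")))),
    "not" = rx_not(expr_from_json(body, paste0(path, ".not"))),
    "true" = rx_true(),
    "finding_is" = finding_is(body$code, body$value %||% "present"),
    "test_is" = test_is(body$code, body$value %||% "positive"),
    "course_in" = course_in(unlist(body)),
    "laterality_in" = laterality_in(unlist(body)),
    "grade_lt" = grade_lt(body$code, body$than),
    "grade_ge" = grade_ge(body$code, body$grade),
    stop("rule DSL error at ", path, ": unknown operator '", key, "'",
         call. = FALSE)
  )
}

expr_to_json <- function(expr) {
  switch(expr$kind,
    "true" = list(true = list()),
    "and" = list(and = lapply(expr$children, expr_to_json)),
    "or" = list(or = lapply(expr$children, expr_to_json)),
    "not" = list(not = expr_to_json(expr$child)),
    "finding_is" = list(finding_is = list(code = expr$code, value = expr$value)),
    "test_is" = list(test_is = list(code = expr$code, value = expr$value)),
    "course_in" = list(course_in = as.list(expr$values)),
    "laterality_in" = list(laterality_in = as.list(expr$values)),
    "grade_lt" = list(grade_lt = list(code = expr$code, than = expr$than)),
    "grade_ge" = list(grade_ge = list(code = expr$code, grade = expr$grade))
  )
}

#' Load and save rule sets in the JSON rule DSL
#'
#' The DSL is a JSON document with top-level keys `disease_id`,
#' `disease_name`, `anatomic_class`, `criteria`, `exclusions` and
#' `provenance`.  Expression nodes are objects with exactly one operator key
#' (`and`, `or`, `not`, `finding_is`, `test_is`, `course_in`,
#' `laterality_in`, `grade_lt`, `grade_ge`, `true`); a `comment` key is
#' ignored.  Schema violations are reported with the JSON path of the
#' offending node; every referenced code must exist in the vocabulary
#' registry.  `load_ruleset(save_ruleset(rs))` is structurally the identity.
#'
#' @param path Path to a rule DSL JSON file.
#' @param rs A `uv_ruleset`.
#' @return `load_ruleset` returns a [rule_set()].
#' @export
load_ruleset <- function(path) {
  doc <- jsonlite::read_json(path)
  for (field in c("disease_id", "disease_name", "anatomic_class", "criteria")) {
    if (is.null(doc[[field]]))
      stop("rule DSL error at $: missing required key '", field, "'",
           call. = FALSE)
  }
  criteria <- expr_from_json(doc$criteria, "$.criteria")
  exclusions <- lapply(seq_along(doc$exclusions), function(i)
    expr_from_json(doc$exclusions[[i]], paste0("$.exclusions[", i, "]")))
  rule_set(doc$disease_id, doc$disease_name, doc$anatomic_class,
           criteria, exclusions, doc$provenance %||% "")
}

#' @rdname load_ruleset
#' @export
save_ruleset <- function(rs, path) {
  doc <- list(disease_id = rs$disease_id, disease_name = rs$disease_name,
              anatomic_class = rs$anatomic_class,
              provenance = rs$provenance,
              criteria = expr_to_json(rs$criteria),
              exclusions = lapply(rs$exclusions, expr_to_json))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' The rule sets shipped with the package
#'
#' Three published criteria sets (SpA/HLA-B27-associated anterior uveitis,
#' Fuchs uveitis syndrome, acute retinal necrosis) plus one clearly marked
#' synthetic stand-in (`synthetic_viral_au`) used by the derivation tests to
#' provide a third anterior disease.
#'
#' @param which Character vector of disease ids; defaults to the three
#'   published rule sets.
#' @return Named list of [rule_set()] objects.
#' @export
#' @examples
#' names(uv_rulesets())
uv_rulesets <- function(which = c("spa_hla_b27", "fuchs_uveitis", "arn")) {
  dir <- system.file("extdata", "rulesets", package = "uveaclass")
  out <- lapply(which, function(id) {
    path <- file.path(dir, paste0(id, ".json"))
    if (!file.exists(path)) stop("no shipped rule set with id '", id, "'",
                                 call. = FALSE)
    load_ruleset(path)
  })
  stats::setNames(out, which)
}
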