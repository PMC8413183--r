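# Case classification ---------------------------------------------------------

#' Classify a case against one or more disease rule sets
#'
#' Evaluates every rule set's criteria tree and each exclusion under Kleene
#' three-valued logic and applies exclusion dominance.  Per rule set the
#' verdict is
#' \describe{
#'   \item{`excluded`}{some exclusion evaluates definitely true -- dominates
#'     everything else;}
#'   \item{`classified`}{criteria are definitely true and no exclusion is
#'     true (an unknown exclusion does not exclude: exclusions demand
#'     positive evidence, an untested patient is not excluded -- but the
#'     trace exposes the `U` so callers can require a completed workup);}
#'   \item{`indeterminate`}{criteria evaluate unknown;}
#'   \item{`criteria_not_met`}{criteria are definitely false.}
#' }
#' Several diseases may classify simultaneously; `final_labels` is a set.
#'
#' @param case A [uv_case()].
#' @param rulesets A single [rule_set()] or a list of them.
#' @return An object of class `uv_classification` with fields `case_id`,
#'   `verdicts` (named character), `trace` (per rule set: the Kleene value
#'   of the criteria tree and of every exclusion) and `final_labels`.
#' @export
#' @examples
#' rs <- uv_rulesets("fuchs_uveitis")
#' cs <- uv_case("F1", laterality = "unilateral",
#'               findings = list(anterior_chamber_cells = "present",
#'                               heterochromia = "present",
#'                               endotheliitis = "absent",
#'                               coin_shaped_endothelial_lesions = "absent",
#'                               active_retinitis = "absent"))
#' classify_case(cs, rs)$final_labels
classify_case <- function(case, rulesets) {
  if (inherits(rulesets, "uv_ruleset")) rulesets <- list(rulesets)
  verdicts <- character(0)
  trace <- list()
  for (rs in rulesets) {
    crit <- eval_expr(rs$criteria, case)
    excl <- vapply(rs$exclusions, eval_expr, "", case = case)
    verdict <- if (any(excl == "T")) "excluded"
      else if (crit == "T") "classified"
      else if (crit == "U") "indeterminate"
      else "criteria_not_met"
    verdicts[[rs$disease_id]] <- verdict
    trace[[rs$disease_id]] <- list(criteria = crit, exclusions = excl)
  }
  structure(list(case_id = case$case_id, verdicts = verdicts, trace = trace,
                 final_labels = names(verdicts)[verdicts == "classified"]),
            class = "uv_classification")
}

#' @export
print.uv_classification <- function(x, ...) {
  cat("<uv_classification>", x$case_id, "\n")
  for (id in names(x$verdicts)) {
    tr <- x$trace[[id]]
    cat(sprintf("  %-20s %-16s criteria=%s exclusions=[%s]\n", id,
                x$verdicts[[id]], tr$criteria, paste(tr$exclusions, collapse = ",")))
  }
  invisible(x)
}

#' Classify every case of a cohort
#'
#' @param cohort A [uv_cohort()].
#' @param rulesets List of [rule_set()] objects.
#' @return List of `uv_classification`, one per case, in cohort order.
#' @export
classify_cohort <- function(cohort, rulesets) {
  lapply(cohort$cases, classify_case, rulesets = rulesets)
}

#' Rule-engine label recovery on a labeled cohort
#'
#' The engine may classify a case into several diseases (the printed rule
#' sets are independent); recovery counts a case as correct when its true
#' label is among the classified labels.
#'
#' @param cohort Labeled [uv_cohort()].
#' @param rulesets List of [rule_set()] objects.
#' @return Proportion of cases whose `true_label` is in `final_labels`.
#' @export
engine_accuracy <- function(cohort, rulesets) {
  res <- classify_cohort(cohort, rulesets)
  labs <- cohort_labels(cohort)
  if (all(is.na(labs))) stop("cohort has no true labels", call. = FALSE)
  hit <- mapply(function(r, lab) !is.na(lab) && lab %in% r$final_labels,
                res, labs)
  mean(hit)
}
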