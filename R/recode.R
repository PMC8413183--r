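# Feature recoding -------------------------------------------------------------
#
# Cases are recoded to a binary feature matrix with a documented,
# deterministic column order: course and laterality one-hot (unknown as its
# own level), then per finding code `<code>=present` and `<code>=unknown`
# indicators (absent = both 0) plus, for gradable findings, cumulative
# indicators `<code>>=1` .. `<code>>=4`, then per test code
# `<code>=positive` and `<code>=unknown`.

feature_columns <- function() {
  cols <- c(paste0("course=", uv_courses()),
            paste0("laterality=", uv_lateralities()))
  for (code in uv_finding_codes()) {
    cols <- c(cols, paste0(code, "=present"), paste0(code, "=unknown"))
    if (uv_is_gradable(code)) cols <- c(cols, paste0(code, ">=", 1:4))
  }
  for (code in uv_test_codes()) {
    cols <- c(cols, paste0(code, "=positive"), paste0(code, "=unknown"))
  }
  cols
}

recode_case_row <- function(case, cols) {
  row <- stats::setNames(integer(length(cols)), cols)
  row[paste0("course=", case$course)] <- 1L
  row[paste0("laterality=", case$laterality)] <- 1L
  for (code in uv_finding_codes()) {
    v <- case_value(case, code)
    if (v == "present") row[paste0(code, "=present")] <- 1L
    if (v == "unknown") row[paste0(code, "=unknown")] <- 1L
    if (uv_is_gradable(code)) {
      g <- case_grade(case, code)
      if (!is.na(g) && g > 0L) row[paste0(code, ">=", seq_len(g))] <- 1L
    }
  }
  for (code in uv_test_codes()) {
    v <- case_value(case, code)
    if (v == "positive") row[paste0(code, "=positive")] <- 1L
    if (v == "unknown") row[paste0(code, "=unknown")] <- 1L
  }
  row
}

#' Recode a labeled cohort into a binary feature matrix
#'
#' @param cohort A labeled [uv_cohort()]; errors if any case lacks
#'   `true_label` (recoding feeds the supervised derivation steps).
#' @return An object of class `uv_features`: list with `x` (n x p binary
#'   matrix, rownames = case ids), `labels` (factor of true labels),
#'   `case_ids` and `split` (carried over from the cohort, possibly NULL).
#' @export
recode <- function(cohort) {
  labs <- cohort_labels(cohort)
  if (any(is.na(labs)))
    stop("recode() needs true_label on every case (supervised step); missing for: ",
         paste(utils::head(cohort_ids(cohort)[is.na(labs)], 3), collapse = ", "),
         call. = FALSE)
  cols <- feature_columns()
  x <- matrix(0L, nrow = length(cohort$cases), ncol = length(cols),
              dimnames = list(cohort_ids(cohort), cols))
  for (i in seq_along(cohort$cases)) x[i, ] <- recode_case_row(cohort$cases[[i]], cols)
  structure(list(x = x, labels = factor(labs), case_ids = cohort_ids(cohort),
                 split = cohort$split), class = "uv_features")
}

#' @export
print.uv_features <- function(x, ...) {
  cat("<uv_features>", nrow(x$x), "cases x", ncol(x$x), "binary features;",
      nlevels(x$labels), "classes\n")
  invisible(x)
}
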