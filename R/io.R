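# Cohort file I/O ------------------------------------------------------------
#
# CSV layout: fixed columns case_id, anatomic_class, course, laterality,
# true_label, then one column per vocabulary code in registry order.  An
# empty cell encodes "unknown"; explicit tri-state tokens are accepted
# case-insensitively; gradable findings serialize as "present:2".

csv_columns <- function() {
  c("case_id", "anatomic_class", "course", "laterality", "true_label",
    uv_finding_codes(), uv_test_codes())
}

parse_finding_token <- function(token, code, where) {
  token <- trimws(token)
  if (!nzchar(token)) return(NULL)
  parts <- strsplit(token, ":", fixed = TRUE)[[1]]
  value <- tolower(parts[1])
  if (!value %in% FINDING_STATES)
    stop(where, ": malformed tri-state token '", token, "' for finding '",
         code, "'", call. = FALSE)
  if (value == "unknown") return(NULL)
  grade <- NULL
  if (length(parts) > 1L) {
    grade <- suppressWarnings(as.integer(parts[2]))
    if (is.na(grade) || grade < 0L || grade > 4L)
      stop(where, ": malformed grade in token '", token, "' for finding '",
           code, "'", call. = FALSE)
  }
  list(value = value, grade = grade)
}

parse_test_token <- function(token, code, where) {
  token <- tolower(trimws(token))
  if (!nzchar(token) || token == "unknown") return(NULL)
  if (!token %in% TEST_STATES)
    stop(where, ": malformed tri-state token '", token, "' for test '",
         code, "'", call. = FALSE)
  token
}

#' Read a case collection from CSV or JSON
#'
#' Every row/document is validated on read; the first invariant violation
#' aborts with a message naming the offending row and field.  Row order is
#' preserved.  An optional `split` column (`train`/`validation`) populates
#' the cohort split.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"json"`; defaults to the file extension.
#' @return A [uv_cohort()].
#' @export
read_cases <- function(path, format = c("csv", "json")) {
  if (missing(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format)
  cohort <- if (format == "csv") read_cases_csv(path) else read_cases_json(path)
  bad <- validate_cohort(cohort)
  if (length(bad)) {
    first <- bad[[1]]
    stop("invalid case '", names(bad)[1], "': ", first[1], call. = FALSE)
  }
  cohort
}

read_cases_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  fixed <- c("case_id", "anatomic_class", "course", "laterality", "true_label")
  missing_cols <- setdiff(fixed, names(df))
  if (length(missing_cols))
    stop("cases CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  known <- c(fixed, "split", uv_finding_codes(), uv_test_codes())
  extra <- setdiff(names(df), known)
  if (length(extra))
    stop("cases CSV has column(s) not in the vocabulary registry: ",
         paste(extra, collapse = ", "), call. = FALSE)
  fcodes <- intersect(uv_finding_codes(), names(df))
  tcodes <- intersect(uv_test_codes(), names(df))
  cases <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    where <- paste0("row ", i)
    findings <- list()
    for (code in fcodes) {
      f <- parse_finding_token(df[[code]][i], code, where)
      if (!is.null(f)) findings[[code]] <- f
    }
    tests <- list()
    for (code in tcodes) {
      t <- parse_test_token(df[[code]][i], code, where)
      if (!is.null(t)) tests[[code]] <- t
    }
    blank_as_unknown <- function(x) if (!nzchar(trimws(x))) "unknown" else trimws(x)
    cases[[i]] <- uv_case(df$case_id[i],
                          anatomic_class = trimws(df$anatomic_class[i]),
                          course = blank_as_unknown(df$course[i]),
                          laterality = blank_as_unknown(df$laterality[i]),
                          findings = findings, tests = tests,
                          true_label = if (nzchar(df$true_label[i])) df$true_label[i] else NULL)
  }
  split <- NULL
  if ("split" %in% names(df) && any(nzchar(df$split))) {
    split <- stats::setNames(df$split, df$case_id)
  }
  uv_cohort(cases, split)
}

read_cases_json <- function(path) {
  docs <- jsonlite::read_json(path)
  if (!is.null(names(docs)) && !is.null(docs$cases)) {
    split_doc <- docs$split
    docs <- docs$cases
  } else split_doc <- NULL
  cases <- lapply(seq_along(docs), function(i) {
    d <- docs[[i]]
    findings <- lapply(d$findings, function(f) {
      if (is.list(f)) list(value = f$value, grade = f$grade) else f
    })
    uv_case(d$case_id,
            anatomic_class = d$anatomic_class %||% "anterior",
            course = d$course %||% "unknown",
            laterality = d$laterality %||% "unknown",
            findings = findings %||% list(),
            tests = d$tests %||% list(),
            true_label = d$true_label)
  })
  split <- if (!is.null(split_doc)) unlist(split_doc) else NULL
  uv_cohort(cases, split)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a case collection to CSV or JSON
#'
#' `read_cases(write_cases(cohort))` is the identity on every field (the
#' case constructor canonicalizes `unknown` entries away, so the round-trip
#' is exact on canonical records).
#'
#' @param cohort A [uv_cohort()].
#' @param path Output path.
#' @param format `"csv"` or `"json"`; defaults to the file extension.
#' @export
write_cases <- function(cohort, path, format = c("csv", "json")) {
  if (missing(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format)
  if (format == "csv") write_cases_csv(cohort, path) else write_cases_json(cohort, path)
  invisible(path)
}

write_cases_csv <- function(cohort, path) {
  fcodes <- uv_finding_codes()
  tcodes <- uv_test_codes()
  cols <- csv_columns()
  if (!is.null(cohort$split)) cols <- c(cols, "split")
  rows <- lapply(cohort$cases, function(cs) {
    row <- stats::setNames(rep("", length(cols)), cols)
    row["case_id"] <- cs$case_id
    row["anatomic_class"] <- cs$anatomic_class
    row["course"] <- if (cs$course == "unknown") "" else cs$course
    row["laterality"] <- if (cs$laterality == "unknown") "" else cs$laterality
    row["true_label"] <- cs$true_label %||% ""
    for (code in names(cs$findings)) {
      f <- cs$findings[[code]]
      row[code] <- if (!is.null(f$grade)) paste0(f$value, ":", f$grade) else f$value
    }
    for (code in names(cs$tests)) row[code] <- cs$tests[[code]]
    if (!is.null(cohort$split)) row["split"] <- cohort$split[[cs$case_id]]
    row
  })
  df <- as.data.frame(do.call(rbind, c(rows, list(deparse.level = 0))),
                      stringsAsFactors = FALSE)
  if (length(rows) == 0L) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  } else names(df) <- cols
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
}

write_cases_json <- function(cohort, path) {
  docs <- lapply(cohort$cases, function(cs) {
    out <- list(case_id = cs$case_id, anatomic_class = cs$anatomic_class,
                course = cs$course, laterality = cs$laterality)
    if (!is.null(cs$true_label)) out$true_label <- cs$true_label
    if (length(cs$findings)) out$findings <- cs$findings
    if (length(cs$tests)) out$tests <- as.list(cs$tests)
    out
  })
  body <- list(cases = docs)
  if (!is.null(cohort$split)) body$split <- as.list(cohort$split)
  jsonlite::write_json(body, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
}
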