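# Controlled vocabulary registry -------------------------------------------

.uv_env <- new.env(parent = emptyenv())

#' Controlled vocabulary of clinical findings and test results
#'
#' The registry is a data file (`inst/extdata/vocabulary.json`) so that new
#' disease rule sets can extend it without touching code.  Findings are
#' tri-state (`present`/`absent`/`unknown`); some carry an ordinal severity
#' grade 0--4 (SUN-style cell grading).  Test results are tri-state
#' (`positive`/`negative`/`unknown`).
#'
#' @param path Optional path to an alternative registry JSON file.
#' @return A data.frame with columns `code`, `kind` (`"finding"`/`"test"`),
#'   `gradable` and `label`, one row per vocabulary entry.
#' @export
#' @examples
#' head(uv_vocabulary())
uv_vocabulary <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.uv_env$vocab)) return(.uv_env$vocab)
    path <- system.file("extdata", "vocabulary.json", package = "uveaclass")
  }
  raw <- jsonlite::read_json(path)
  fin <- do.call(rbind, lapply(raw$findings, function(f) {
    data.frame(code = f$code, kind = "finding",
               gradable = isTRUE(f$gradable), label = f$label,
               stringsAsFactors = FALSE)
  }))
  tst <- do.call(rbind, lapply(raw$tests, function(t) {
    data.frame(code = t$code, kind = "test", gradable = FALSE,
               label = t$label, stringsAsFactors = FALSE)
  }))
  vocab <- rbind(fin, tst)
  if (anyDuplicated(vocab$code)) {
    stop("vocabulary registry contains duplicate codes", call. = FALSE)
  }
  .uv_env$vocab <- vocab
  vocab
}

uv_finding_codes <- function() {
  v <- uv_vocabulary()
  v$code[v$kind == "finding"]
}

uv_test_codes <- function() {
  v <- uv_vocabulary()
  v$code[v$kind == "test"]
}

uv_is_gradable <- function(code) {
  v <- uv_vocabulary()
  i <- match(code, v$code)
  !is.na(i) & v$gradable[i]
}

uv_code_kind <- function(code) {
  v <- uv_vocabulary()
  v$kind[match(code, v$code)]
}

#' @rdname uv_vocabulary
#' @format NULL
#' @export
uv_anatomic_classes <- function() {
  c("anterior", "intermediate", "posterior", "panuveitis", "infectious_post_pan")
}

uv_courses <- function() {
  c("acute", "recurrent_acute", "chronic", "chronic_after_recurrent_acute", "unknown")
}

uv_lateralities <- function() {
  c("unilateral", "alternating_unilateral", "bilateral", "unknown")
}

FINDING_STATES <- c("present", "absent", "unknown")
TEST_STATES <- c("positive", "negative", "unknown")
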