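# Accuracy reporting ------------------------------------------------------------

#' Wilson score confidence interval for a proportion
#'
#' @param k Number of successes.
#' @param n Number of trials (> 0).
#' @param conf Confidence level (default 0.95).
#' @return Named vector `c(low, high)`, both in \[0, 1\].
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n > 0, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  phat <- k / n
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, center - half), high = min(1, center + half))
}

#' Clopper-Pearson (exact) confidence interval for a proportion
#'
#' @inheritParams wilson_ci
#' @return Named vector `c(low, high)`.
#' @export
clopper_pearson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n > 0, k >= 0, k <= n)
  a <- (1 - conf) / 2
  low <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  high <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(low = low, high = high)
}

#' Per-stratum accuracy report with per-disease misclassification rates
#'
#' Emulates the published reporting format: overall accuracy of the
#' predicted labels against the consensus/true labels with a Wilson 95\%
#' confidence interval, plus, per disease, the misclassification rate
#' (1 - recall of that disease) with its own Wilson interval, and the full
#' confusion matrix (rows = true label, columns = predicted).
#'
#' @param predicted,truth Equal-length label vectors (non-empty).
#' @param stratum Label for the anatomic-class stratum being reported.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `uv_accuracy`: `stratum`, `n`,
#'   `overall_accuracy`, `ci95`, `per_disease` (data.frame with `n`,
#'   `misclassification`, `ci_low`, `ci_high`) and `confusion`.
#' @export
accuracy_report <- function(predicted, truth, stratum = "all", conf = 0.95) {
  if (length(predicted) == 0L || length(truth) == 0L)
    stop("accuracy_report needs non-empty label vectors", call. = FALSE)
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length", call. = FALSE)
  lev <- sort(unique(c(as.character(predicted), as.character(truth))))
  predicted <- factor(as.character(predicted), levels = lev)
  truth <- factor(as.character(truth), levels = lev)
  confusion <- table(truth = truth, predicted = predicted)
  n <- length(truth)
  correct <- sum(diag(confusion))
  ci <- wilson_ci(correct, n, conf)
  per <- do.call(rbind, lapply(lev, function(d) {
    nd <- sum(confusion[d, ])
    if (nd == 0) return(data.frame(disease = d, n = 0L,
                                   misclassification = NA_real_,
                                   ci_low = NA_real_, ci_high = NA_real_))
    miss <- nd - confusion[d, d]
    wc <- wilson_ci(miss, nd, conf)
    data.frame(disease = d, n = nd, misclassification = miss / nd,
               ci_low = wc[["low"]], ci_high = wc[["high"]])
  }))
  rownames(per) <- NULL
  structure(list(stratum = stratum, n = n, overall_accuracy = correct / n,
                 ci95 = ci, per_disease = per, confusion = confusion),
            class = "uv_accuracy")
}

#' @export
print.uv_accuracy <- function(x, ...) {
  cat(sprintf("<uv_accuracy> stratum %s: accuracy %.1f%% (95%% CI %.1f-%.1f), n=%d\n",
              x$stratum, 100 * x$overall_accuracy, 100 * x$ci95[["low"]],
              100 * x$ci95[["high"]], x$n))
  for (i in seq_len(nrow(x$per_disease))) {
    r <- x$per_disease[i, ]
    if (r$n > 0)
      cat(sprintf("  %-24s misclassification %.1f%% (95%% CI %.1f-%.1f), n=%d\n",
                  r$disease, 100 * r$misclassification, 100 * r$ci_low,
                  100 * r$ci_high, r$n))
  }
  invisible(x)
}
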