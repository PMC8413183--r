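# Shadow-feature (Boruta-style) all-relevant selection ------------------------

#' Select decisive features by comparison against permuted shadow copies
#'
#' Each iteration appends a column-permuted shadow copy of every feature,
#' scores all columns with the bagged-tree ensemble (out-of-bag permutation
#' importance summarized as a Z score, mean/standard error over trees), and
#' records a *hit* for every real feature whose Z score exceeds the maximum
#' shadow Z score.  Under the null a feature hits with probability 1/2, so
#' after `n_iter` iterations each feature's hit count is tested two-sided
#' against Binomial(n_iter, 1/2) at level `alpha` with Bonferroni correction
#' across features: significantly many hits confirms, significantly few
#' rejects, otherwise the feature stays tentative.
#'
#' @param x Binary feature matrix (n x p) with column names.
#' @param y Class labels (factor or coercible); at least two classes.
#' @param n_iter Number of shadow iterations (default 100).
#' @param alpha Two-sided significance level (default 0.01).
#' @param n_trees Trees per ensemble (default 500).
#' @param mtry Features sampled per split; default `floor(sqrt(2p))`.
#' @param min_node Minimal node size to attempt a split (default 5).
#' @param seed Optional integer seed; selection is deterministic given it.
#' @return A data.frame with columns `feature`, `hits`, `n_iter`, `p_value`
#'   and `status` (`confirmed`/`rejected`/`tentative`), ordered like the
#'   columns of `x`.
#' @export
boruta_select <- function(x, y, n_iter = 100L, alpha = 0.01, n_trees = 500L,
                          mtry = NULL, min_node = 5L, seed = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  y <- factor(y)
  if (nlevels(y) < 2L)
    stop("boruta_select needs at least two classes in y", call. = FALSE)
  if (nrow(x) < 20L)
    stop("boruta_select needs n >= 20 cases", call. = FALSE)
  p <- ncol(x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(2 * p)))
  if (!is.null(seed)) set.seed(seed)
  yi <- as.integer(y) - 1L
  hits <- integer(p)
  for (iter in seq_len(n_iter)) {
    shadow <- apply(x, 2, sample)
    xs <- cbind(x, shadow)
    imp <- forest_importance_cpp(xs, yi, nlevels(y), as.integer(n_trees),
                                 as.integer(mtry), as.integer(min_node))
    z <- apply(imp, 2, function(col) {
      s <- stats::sd(col)
      if (!is.finite(s) || s == 0) 0 else mean(col) / (s / sqrt(length(col)))
    })
    hits <- hits + (z[seq_len(p)] > max(z[p + seq_len(p)]))
  }
  p_hi <- stats::pbinom(hits - 1L, n_iter, 0.5, lower.tail = FALSE)
  p_lo <- stats::pbinom(hits, n_iter, 0.5)
  p_value <- pmin(1, 2 * pmin(p_hi, p_lo))
  thresh <- alpha / p  # Bonferroni across features
  status <- rep("tentative", p)
  if (n_iter > 0L) {
    status[p_value < thresh & hits > n_iter / 2] <- "confirmed"
    status[p_value < thresh & hits < n_iter / 2] <- "rejected"
  }
  data.frame(feature = colnames(x) %||% paste0("V", seq_len(p)),
             hits = hits, n_iter = as.integer(n_iter), p_value = p_value,
             status = status, stringsAsFactors = FALSE)
}
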