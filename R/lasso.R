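# Multinomial lasso classification ---------------------------------------------
#
# The classifier minimizes the mean negative multinomial log-likelihood plus
# an L1 penalty on the slope coefficients (intercepts unpenalized); the fit
# is delegated to glmnet, the field-standard implementation of that
# objective, but coefficients are extracted into a self-contained model
# object and predictions are computed here from the stored coefficients.

#' Fit a multinomial logistic regression with lasso regularization
#'
#' @param x Binary feature matrix (n x p) with column names (typically the
#'   Boruta-confirmed columns of a [recode()] matrix).
#' @param y Class labels; at least two classes must be present.
#' @param lambda Either a non-negative penalty value or `"cv"` (default):
#'   choose the penalty by stratified k-fold cross-validated deviance with
#'   the one-standard-error rule.
#' @param nfolds Folds for cross-validation (default 5).
#' @param seed Optional seed controlling fold assignment.
#' @return An object of class `uv_model`: `classes`, `feature_names`,
#'   `beta` (p x K), `intercepts` (length K), `lambda`, `selected_features`
#'   (columns with a nonzero coefficient in any class).
#' @export
fit_multinomial_lasso <- function(x, y, lambda = "cv", nfolds = 5L, seed = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- factor(y)
  if (nlevels(y) < 2L)
    stop("fit_multinomial_lasso needs at least two classes present",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (identical(lambda, "cv")) {
    foldid <- integer(length(y))
    for (cl in levels(y)) {            # stratified fold assignment
      idx <- sample(which(y == cl))
      foldid[idx] <- rep_len(seq_len(nfolds), length(idx))
    }
    cv <- glmnet::cv.glmnet(x, y, family = "multinomial", alpha = 1,
                            standardize = FALSE, foldid = foldid,
                            type.measure = "deviance")
    lambda <- cv$lambda.1se            # one-standard-error rule
    fit <- cv$glmnet.fit
  } else {
    stopifnot(is.numeric(lambda), lambda >= 0)
    fit <- glmnet::glmnet(x, y, family = "multinomial", alpha = 1,
                          standardize = FALSE)
  }
  cf <- glmnet::coef.glmnet(fit, s = lambda)
  K <- nlevels(y)
  beta <- matrix(0, nrow = ncol(x), ncol = K,
                 dimnames = list(colnames(x), levels(y)))
  intercepts <- stats::setNames(numeric(K), levels(y))
  for (k in seq_len(K)) {
    ck <- as.matrix(cf[[k]])
    intercepts[k] <- ck[1, 1]
    beta[, k] <- ck[-1, 1]
  }
  structure(list(classes = levels(y), feature_names = colnames(x),
                 beta = beta, intercepts = intercepts, lambda = lambda,
                 selected_features = rownames(beta)[rowSums(abs(beta)) > 0]),
            class = "uv_model")
}

#' Smallest penalty that zeroes every coefficient
#'
#' For the multinomial lasso with unpenalized intercepts, the null model
#' (all slopes zero, intercepts at the class log-frequencies) is optimal iff
#' the penalty dominates every component of the loss gradient at zero:
#' `lambda_max = max_{j,k} | mean_i x_ij (1\[y_i = k\] - pbar_k) |` with
#' `pbar_k` the class frequencies.
#'
#' @inheritParams fit_multinomial_lasso
#' @return The penalty bound (a single number).
#' @export
lambda_max <- function(x, y) {
  x <- as.matrix(x)
  y <- factor(y)
  n <- nrow(x)
  pbar <- as.vector(table(y)) / n
  ind <- outer(y, levels(y), `==`) * 1.0   # n x K indicator
  resid <- sweep(ind, 2, pbar)             # 1[y=k] - pbar_k
  max(abs(crossprod(x, resid) / n))
}

#' Predict class probabilities and labels from a fitted model
#'
#' Probabilities are the softmax of `intercepts + x %*% beta`; every row
#' sums to one.  The label is the argmax, with ties broken toward the first
#' class in `model$classes` (the documented, deterministic rule -- also the
#' teacher tie-break used by distillation).
#'
#' @param object A `uv_model`.
#' @param x Feature matrix whose columns match `object$feature_names`.
#' @param ... Unused.
#' @return List with `prob` (n x K matrix) and `label` (factor).
#' @export
predict.uv_model <- function(object, x, ...) {
  x <- as.matrix(x)
  if (!identical(colnames(x), object$feature_names)) {
    if (is.null(colnames(x)) || !all(object$feature_names %in% colnames(x)))
      stop("feature columns do not match the model's feature_names",
           call. = FALSE)
    x <- x[, object$feature_names, drop = FALSE]
  }
  eta <- sweep(x %*% object$beta, 2, object$intercepts, "+")
  eta <- eta - apply(eta, 1, max)          # numerical stability
  ex <- exp(eta)
  prob <- ex / rowSums(ex)
  colnames(prob) <- object$classes
  label <- factor(object$classes[apply(prob, 1, which.max)],
                  levels = object$classes)
  list(prob = prob, label = label)
}

#' @export
print.uv_model <- function(x, ...) {
  cat("<uv_model> multinomial lasso:", length(x$classes), "classes,",
      length(x$feature_names), "features,",
      length(x$selected_features), "with nonzero coefficients; lambda =",
      signif(x$lambda, 4), "\n")
  invisible(x)
}

#' Save / load a fitted model as JSON
#'
#' @param model A `uv_model`.
#' @param path File path.
#' @return `load_model` returns the `uv_model`.
#' @export
save_model <- function(model, path) {
  doc <- list(classes = model$classes, feature_names = model$feature_names,
              beta = as.data.frame(model$beta),
              intercepts = as.list(model$intercepts),
              lambda = model$lambda,
              selected_features = model$selected_features)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- as.matrix(doc$beta)
  rownames(beta) <- doc$feature_names
  colnames(beta) <- doc$classes
  structure(list(classes = doc$classes, feature_names = doc$feature_names,
                 beta = beta, intercepts = unlist(doc$intercepts),
                 lambda = doc$lambda,
                 selected_features = doc$selected_features %||% character(0)),
            class = "uv_model")
}
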