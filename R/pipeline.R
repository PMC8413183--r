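# End-to-end derivation pipeline ----------------------------------------------
#
# Phase I: recode + shadow-feature selection + multinomial lasso per
# anatomic class; Phase II: validation on held-out cases; Phase III:
# distillation into a logical rule system that makes the same decision as
# the model.  Driven by a config (list, or YAML/JSON file) naming either a
# case file or a simulation spec.

read_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML configs need the 'yaml' package; use JSON instead",
             call. = FALSE)
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  config
}

resolve_rulesets <- function(specs) {
  shipped <- c("spa_hla_b27", "fuchs_uveitis", "arn", "synthetic_viral_au")
  out <- lapply(specs, function(s) {
    if (s %in% shipped) uv_rulesets(s)[[1]] else load_ruleset(s)
  })
  stats::setNames(out, vapply(out, `[[`, "", "disease_id"))
}

pipeline_cohort <- function(config) {
  if (!is.null(config$cases)) {
    cohort <- read_cases(config$cases)
    if (is.null(cohort$split)) {
      tf <- config$train_fraction %||% stop("case file has no split column; ",
        "set train_fraction in the config", call. = FALSE)
      if (!(tf > 0 && tf < 1))
        stop("split stage: train_fraction must be strictly between 0 and 1",
             call. = FALSE)
      labs <- cohort_labels(cohort)
      split <- rep("validation", length(labs))
      for (d in unique(labs)) {
        idx <- which(labs == d)
        split[sample(idx, round(tf * length(idx)))] <- "train"
      }
      cohort$split <- stats::setNames(split, cohort_ids(cohort))
    }
    return(cohort)
  }
  if (is.null(config$simulate))
    stop("config must name either 'cases' or a 'simulate' block", call. = FALSE)
  sim <- config$simulate
  spec <- cohort_spec(resolve_rulesets(sim$rulesets),
                      n_cases = sim$n_cases,
                      weights = sim$weights %||% NULL,
                      flip_noise = sim$flip_noise %||% 0,
                      missing_rate = sim$missing_rate %||% 0,
                      train_fraction = sim$train_fraction %||% (2 / 3),
                      seed = config$seed %||% 1L,
                      background_rate = sim$background_rate %||% 0.05)
  generate_cohort(spec)
}

#' Run the full derivation pipeline
#'
#' Executes simulate/load -> split -> recode -> select -> fit -> validate ->
#' distill -> report, separately per anatomic class, and writes all
#' artifacts (cases, per-class model and distilled rules in the rule DSL,
#' confusion matrices, a JSON report) under `out_dir`.  Fully deterministic
#' given `config$seed`.
#'
#' @param config A list, or path to a YAML/JSON file, with entries:
#'   `seed`; either `cases` (path to a case file) or `simulate`
#'   (`rulesets`, `n_cases`, `flip_noise`, `missing_rate`,
#'   `train_fraction`, `background_rate`, `weights`); optional `boruta`
#'   (`n_iter`, `alpha`, `n_trees`) and `lambda` (number or `"cv"`),
#'   `nfolds`.
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing artifacts.
#' @return The report, invisibly also written as `report.json`: per
#'   anatomic class the sample sizes, selected features, penalty, train and
#'   validation accuracy with 95\% CIs, per-disease misclassification
#'   rates, confusion matrices and distillation agreement.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- read_config(config)
  seed <- as.integer(config$seed %||% 1L)
  set.seed(seed)
  cohort <- pipeline_cohort(config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cases(cohort, file.path(out_dir, "cases.csv"))
  }
  classes <- unique(vapply(cohort$cases, `[[`, "", "anatomic_class"))
  boruta_cfg <- config$boruta %||% list()
  report <- list(seed = seed, n_cases = length(cohort), strata = list())
  for (ac in classes) {
    message("stratum '", ac, "': recoding")
    sub <- cohort_subset(cohort, vapply(cohort$cases, function(cs)
      cs$anatomic_class == ac, TRUE))
    feats <- recode(sub)
    if (nlevels(droplevels(feats$labels)) < 2L) {
      message("stratum '", ac, "': fewer than two diseases, skipped")
      next
    }
    train <- feats$split == "train"
    if (!any(train) || !any(!train))
      stop("stage split: stratum '", ac, "' has an empty train or validation set",
           call. = FALSE)
    xtr <- feats$x[train, , drop = FALSE]
    ytr <- droplevels(feats$labels[train])
    message("stratum '", ac, "': shadow-feature selection")
    sel <- boruta_select(xtr, ytr,
                         n_iter = boruta_cfg$n_iter %||% 100L,
                         alpha = boruta_cfg$alpha %||% 0.01,
                         n_trees = boruta_cfg$n_trees %||% 500L,
                         seed = seed + 1L)
    confirmed <- sel$feature[sel$status == "confirmed"]
    if (!length(confirmed))
      stop("stage select: no feature confirmed in stratum '", ac, "'",
           call. = FALSE)
    message("stratum '", ac, "': fitting multinomial lasso on ",
            length(confirmed), " features")
    model <- fit_multinomial_lasso(xtr[, confirmed, drop = FALSE], ytr,
                                   lambda = config$lambda %||% "cv",
                                   nfolds = config$nfolds %||% 5L,
                                   seed = seed + 2L)
    pred_tr <- predict(model, xtr[, confirmed, drop = FALSE])$label
    xva <- feats$x[!train, confirmed, drop = FALSE]
    pred_va <- predict(model, xva)$label
    rep_tr <- accuracy_report(pred_tr, ytr, stratum = ac)
    rep_va <- accuracy_report(pred_va, feats$labels[!train], stratum = ac)
    message("stratum '", ac, "': distilling rules")
    feats_sub <- feats
    dist <- distill(model, feats_sub)
    if (!is.null(out_dir)) {
      save_model(model, file.path(out_dir, paste0("model_", ac, ".json")))
      derived <- lapply(model$classes, function(cl)
        rule_set(paste0(cl, "_derived"), paste0("distilled rule for ", cl),
                 ac, dist$rules[[cl]], exclusions = list(),
                 provenance = "distilled from the fitted multinomial lasso"))
      for (rs in derived)
        save_ruleset(rs, file.path(out_dir,
          paste0("rules_derived_", rs$disease_id, ".json")))
      utils::write.csv(as.data.frame.matrix(rep_va$confusion),
                       file.path(out_dir, paste0("confusion_", ac, ".csv")))
    }
    report$strata[[ac]] <- list(
      n_train = sum(train), n_validation = sum(!train),
      confirmed_features = confirmed, lambda = model$lambda,
      train = list(accuracy = rep_tr$overall_accuracy,
                   ci95 = as.list(rep_tr$ci95),
                   per_disease = rep_tr$per_disease),
      validation = list(accuracy = rep_va$overall_accuracy,
                        ci95 = as.list(rep_va$ci95),
                        per_disease = rep_va$per_disease,
                        confusion = as.data.frame.matrix(rep_va$confusion)),
      distillation = list(agreement = as.list(dist$agreement),
                          complexity = as.list(dist$complexity),
                          disagreements = dist$disagreements))
  }
  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
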