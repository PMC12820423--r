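#' Reference decomposition table
#'
#' Published decomposition of inequality in breast-cancer screening uptake
#' among Indian women aged 30-49 (NFHS-5), shipped as a plain-text
#' fixture: per rank variable and feature, the normalised feature
#' importance, the feature-specific concentration index with its SE, and
#' the printed product-rule contribution with the number of printed
#' decimals. The `consistent` flag marks rows whose printed contribution
#' exactly equals the rounded product of the printed factors; a few
#' printed cells are internally inconsistent with their own factors and
#' are flagged `FALSE`.
#'
#' @return Data frame with 60 rows.
#' @export
decomposition_reference <- function() {
  utils::read.csv(
    system.file("extdata", "reference_decomposition.csv",
                package = "screenineq"),
    stringsAsFactors = FALSE
  )
}

#' Pipeline run configuration
#'
#' @param input Optional path to a survey CSV ([read_survey_csv()]); when
#'   `NULL` the NFHS-like generator preset is used.
#' @param n_records Records to generate when simulating.
#' @param seed Master seed for every stage.
#' @param models Classifier kinds to fit and compare.
#' @param single_learner Kind used for attribution, predicted CIs and
#'   decomposition (default `"decision-tree"`, the most stable learner).
#' @param ratio,k Train fraction and number of cross-validation folds.
#' @param smote_k SMOTE nearest-neighbour count.
#' @param smote_in_folds Apply oversampling inside each training fold only
#'   instead of once before splitting (controls resampling leakage;
#'   default FALSE replicates the original design).
#' @param n_splits Repeated splits for the stability analysis.
#' @param rank_variables Rank variables for the inequality stages.
#' @param conf Confidence level for CI bounds.
#' @param n_explain,n_background,n_perm SHAP sample sizes: records
#'   explained, background rows, sampled orderings.
#' @param bootstrap_B Bootstrap replicates for decomposition uncertainty
#'   (0 disables the bootstrap stage).
#' @param out_dir Output directory for tables and JSON (`NULL`: return
#'   results only, write nothing).
#' @return List of class `"run_config"`.
#' @export
run_config <- function(input = NULL, n_records = 50000L, seed = 1L,
                       models = .model_kinds,
                       single_learner = "decision-tree",
                       ratio = 0.8, k = 10L, smote_k = 5L,
                       smote_in_folds = FALSE, n_splits = 10L,
                       rank_variables = c("wealth_quintile",
                                          "education_level", "ethnicity"),
                       conf = 0.95, n_explain = 300L, n_background = 100L,
                       n_perm = 25L, bootstrap_B = 0L, out_dir = NULL) {
  structure(
    list(input = input, n_records = as.integer(n_records),
         seed = as.integer(seed), models = models,
         single_learner = single_learner, ratio = ratio,
         k = as.integer(k), smote_k = as.integer(smote_k),
         smote_in_folds = isTRUE(smote_in_folds),
         n_splits = as.integer(n_splits),
         rank_variables = rank_variables, conf = conf,
         n_explain = as.integer(n_explain),
         n_background = as.integer(n_background),
         n_perm = as.integer(n_perm),
         bootstrap_B = as.integer(bootstrap_B), out_dir = out_dir),
    class = "run_config"
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full inequality-decomposition pipeline
#'
#' End-to-end workflow: load or simulate the survey table; bivariate
#' weighted associations with the outcome; encode, oversample the
#' minority class and split; fit and evaluate the classifier families and
#' run the repeated-split stability analysis for the tree-based learners;
#' compute permutation and SHAP importance for the single learner;
#' estimate observed-outcome and model-predicted concentration indices by
#' each rank variable; and decompose the predicted-probability inequality
#' by the product rule and by Shapley-rank covariances. When `out_dir` is
#' set, each table is written as CSV and every number is consolidated into
#' one JSON file alongside the archived configuration.
#'
#' @param config A [run_config()].
#' @return List of class `"pipeline_result"` with components
#'   `associations`, `metrics`, `stability`, `importance`, `ci_table`,
#'   `decomposition` (per rank variable), `shap_decomposition` (per rank
#'   variable), `cv` (base vs final cross-validated AUROC) and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  tab <- .stage("data", {
    if (is.null(config$input)) {
      generate_survey(nfhs_like_preset(config$n_records, seed = seed))
    } else read_survey_csv(config$input)
  })

  associations <- .stage("associations", {
    vars <- intersect(
      c("wealth_quintile", "education_level", "ethnicity", "residence",
        "met_chw", "female_provider_unavailable", "distance_problem",
        "transport_problem", "money_for_treatment", "safe_water",
        "sanitation", "pqc_index"),
      names(tab))
    do.call(rbind, lapply(vars, function(v) {
      a <- bivariate_association(tab, v)
      a$chi2 <- attr(a, "chi2"); a$df <- attr(a, "df"); a$p <- attr(a, "p")
      a
    }))
  })

  enc <- .stage("preprocess", encode_features(tab))
  bal <- .stage("resample", if (config$smote_in_folds) enc else
    smote_oversample(enc, k_neighbors = config$smote_k, seed = seed))
  plan <- .stage("split", make_splits(bal, ratio = config$ratio,
                                      k = config$k, seed = seed))
  train <- slice_records(bal, plan$train_idx)
  test <- slice_records(bal, plan$test_idx)

  metrics <- .stage("fit-evaluate", {
    do.call(rbind, lapply(config$models, function(kind) {
      tr <- train
      if (config$smote_in_folds)
        tr <- smote_oversample(tr, k_neighbors = config$smote_k,
                               seed = seed)
      model <- fit_model(kind, tr, seed = seed)
      cbind(data.frame(model = kind), .metrics_row(evaluate(model, test)))
    }))
  })

  cv <- .stage("cross-validate", {
    base <- cross_validate(bal, config$single_learner, plan, seed = seed,
                           feature_set = "base")
    final <- cross_validate(bal, config$single_learner, plan, seed = seed,
                            feature_set = "all")
    list(base_auroc = base$pooled_auroc, final_auroc = final$pooled_auroc,
         base_folds = base$fold_metrics, final_folds = final$fold_metrics)
  })

  stability <- .stage("stability", {
    kinds <- intersect(c("random-forest", "decision-tree",
                         "gradient-boosted-trees"), config$models)
    stability_analysis(bal, kinds, n_splits = config$n_splits,
                       seed = seed, ratio = config$ratio)
  })

  learner <- .stage("single-learner",
                    fit_model(config$single_learner, train, seed = seed))

  attribution <- .stage("attribute", {
    set.seed(seed + 1L)
    n_ex <- min(config$n_explain, length(plan$test_idx))
    ex_idx <- sort(sample(seq_along(plan$test_idx), n_ex))
    bg_idx <- sort(sample(seq_along(plan$train_idx),
                          min(config$n_background,
                              length(plan$train_idx))))
    explained <- slice_records(test, ex_idx)
    shap <- shap_values(learner, explained, slice_records(train, bg_idx),
                        n_perm = config$n_perm, seed = seed)
    perm <- permutation_importance(learner, test, n_repeats = 5L,
                                   seed = seed)
    list(shap = shap, shap_importance = shap_mean_abs(shap),
         permutation = perm, explained = explained)
  })

  importance_table <- .stage("importance-table", {
    si <- attribution$shap_importance
    pi <- attribution$permutation
    data.frame(feature = si$feature,
               mean_abs_shap = si$raw,
               shap_importance = si$normalized,
               permutation_importance = pi$raw[match(si$feature,
                                                     pi$feature)],
               stringsAsFactors = FALSE)
  })

  ci_table <- .stage("concentration-indices", {
    do.call(rbind, lapply(config$rank_variables, function(rv) {
      spec <- rank_spec(rv)
      R <- fractional_rank(tab[[rv]], tab$w, spec)
      obs <- ci_convenient_regression(tab$y, R, conf = config$conf)
      prd <- ci_from_predictions(learner, enc, spec, conf = config$conf)
      data.frame(
        rank_variable = rv,
        observed_ci = obs$ci, observed_se = obs$se,
        observed_lower = obs$lower, observed_upper = obs$upper,
        observed_stars = obs$stars,
        predicted_ci = prd$ci, predicted_se = prd$se,
        predicted_lower = prd$lower, predicted_upper = prd$upper,
        predicted_stars = prd$stars,
        stringsAsFactors = FALSE)
    }))
  })

  decomposition <- .stage("decompose", {
    out <- list()
    for (rv in config$rank_variables) {
      spec <- rank_spec(rv)
      R <- fractional_rank(tab[[rv]], tab$w, spec)
      fcis <- feature_ci_encoded(enc, R, conf = config$conf)
      total <- ci_from_predictions(learner, enc, spec,
                                   conf = config$conf)$ci
      out[[rv]] <- product_decomposition(attribution$shap_importance,
                                         fcis, rv, total_ci = total)
    }
    out
  })

  shap_decomposition <- .stage("shap-decompose", {
    ex <- attribution$explained
    out <- list()
    for (rv in config$rank_variables) {
      spec <- rank_spec(rv)
      vals <- .rank_values(ex, rv, levels = spec$ordering)
      R <- fractional_rank(vals, ex$w, spec)
      out[[rv]] <- shap_rank_decomposition(attribution$shap, R)
    }
    out
  })

  result <- structure(
    list(associations = associations, metrics = metrics,
         stability = stability, importance = importance_table,
         ci_table = ci_table, decomposition = decomposition,
         shap_decomposition = shap_decomposition, cv = cv,
         config = config),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline_outputs(result)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Screening-inequality pipeline result\n")
  cat(sprintf("  base-model CV AUROC %.3f -> final-model CV AUROC %.3f\n",
              x$cv$base_auroc, x$cv$final_auroc))
  print(x$ci_table[, c("rank_variable", "observed_ci", "predicted_ci")],
        row.names = FALSE)
  invisible(x)
}

#' Write pipeline tables and consolidated JSON
#'
#' Emits one CSV per table (associations, metrics, stability log and
#' summary, importance, concentration indices, one decomposition table
#' per rank variable) plus `results.json` holding every number and
#' `config.json` archiving the run configuration.
#'
#' @param result A `"pipeline_result"`.
#' @return The output directory, invisibly.
#' @export
write_pipeline_outputs <- function(result) {
  dir <- result$config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                        row.names = FALSE)
  wr(result$associations, "associations.csv")
  wr(result$metrics, "metrics.csv")
  wr(result$stability$log, "stability_splits.csv")
  wr(result$stability$summary, "stability_summary.csv")
  wr(result$importance, "importance.csv")
  wr(result$ci_table, "concentration_indices.csv")
  for (rv in names(result$decomposition))
    wr(result$decomposition[[rv]]$rows,
       sprintf("decomposition_%s.csv", rv))

  json <- list(
    config = unclass(result$config),
    cv = list(base_auroc = result$cv$base_auroc,
              final_auroc = result$cv$final_auroc),
    metrics = result$metrics,
    stability_summary = result$stability$summary,
    importance = result$importance,
    concentration_indices = result$ci_table,
    decomposition = lapply(result$decomposition, function(d)
      list(rows = d$rows, total_ci = d$total_ci, sum_d = d$sum_d,
           residual = d$residual)),
    shap_decomposition = lapply(result$shap_decomposition, function(d)
      list(contributions = as.list(d$contributions),
           total_ci = d$total_ci, residual = d$residual))
  )
  jsonlite::write_json(json, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(result$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
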