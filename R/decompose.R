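#' Concentration index of a single feature
#'
#' Concentration index of a feature's numeric encoding over the fractional
#' ranks of a rank variable (the "feature-specific inequality"). Ordinal
#' and binary features use their integer scores; for nominal features the
#' per-level indicator CIs are aggregated by level prevalence. A feature
#' whose weighted mean is not positive is mean-shifted by +1 when
#' `shift_nonpositive` is set (recorded on the result), otherwise refused.
#'
#' @param feature Numeric vector (or, via [feature_ci_encoded()], a
#'   variable of an encoded matrix).
#' @param R A [fractional_rank()] object.
#' @param conf Confidence level for the convenient-regression bounds.
#' @param shift_nonpositive Mean-shift degenerate features by +1
#'   (default TRUE).
#' @return A `"concindex"` with method `"feature"`; attribute `"shifted"`
#'   marks mean-shifted features.
#' @export
feature_ci <- function(feature, R, conf = 0.95, shift_nonpositive = TRUE) {
  stopifnot(inherits(R, "fractional_ranks"))
  shifted <- FALSE
  mu <- .wmean(feature, R$w)
  if (mu <= 0) {
    if (!shift_nonpositive)
      stop("feature has nonpositive weighted mean; CI undefined",
           call. = FALSE)
    feature <- feature + 1
    shifted <- TRUE
    if (.wmean(feature, R$w) <= 0)
      stop("feature mean still nonpositive after +1 shift", call. = FALSE)
  }
  if (stats::var(feature) == 0) {
    # constant feature: CI is exactly 0 with no sampling variation
    out <- structure(
      list(ci = 0, se = 0, lower = 0, upper = 0, conf = conf,
           p_value = NA_real_, stars = "", method = "feature",
           rank_variable = R$spec$rank_variable, n = length(feature),
           mu = .wmean(feature, R$w)),
      class = "concindex"
    )
    attr(out, "shifted") <- shifted
    return(out)
  }
  out <- ci_convenient_regression(feature, R, conf = conf,
                                  method = "feature")
  attr(out, "shifted") <- shifted
  out
}

#' Feature concentration indices for every variable of an encoded matrix
#'
#' @param data An `"encoded_matrix"`.
#' @param R A [fractional_rank()] object for `nrow(data$X)` records.
#' @param conf Confidence level.
#' @return Named list of `"concindex"` objects, one per variable (nominal
#'   variables: prevalence-weighted aggregate of per-level indicator CIs).
#' @export
feature_ci_encoded <- function(data, R, conf = 0.95) {
  stopifnot(inherits(data, "encoded_matrix"))
  out <- list()
  for (nm in names(data$encoding_map)) {
    m <- data$encoding_map[[nm]]
    if (m$type == "onehot" && length(m$columns) > 1L) {
      # aggregate per-level indicator CIs by level prevalence
      block <- data$X[, m$columns, drop = FALSE]
      prev <- apply(block, 2L, .wmean, w = R$w)
      keep <- prev > 0
      cis <- lapply(which(keep), function(k)
        feature_ci(block[, k], R, conf = conf))
      wsum <- sum(prev[keep])
      agg_ci <- sum(prev[keep] / wsum *
                      vapply(cis, `[[`, numeric(1), "ci"))
      agg_se <- sqrt(sum((prev[keep] / wsum)^2 *
                           vapply(cis, `[[`, numeric(1), "se")^2))
      z <- stats::qnorm(1 - (1 - conf) / 2)
      p <- if (agg_se > 0) 2 * stats::pnorm(-abs(agg_ci / agg_se))
      else NA_real_
      out[[nm]] <- structure(
        list(ci = agg_ci, se = agg_se, lower = agg_ci - z * agg_se,
             upper = agg_ci + z * agg_se, conf = conf, p_value = p,
             stars = .stars(p), method = "feature",
             rank_variable = R$spec$rank_variable, n = nrow(block),
             mu = NA_real_),
        class = "concindex"
      )
    } else {
      out[[nm]] <- feature_ci(data$X[, m$columns], R, conf = conf)
    }
  }
  out
}

#' Product-rule decomposition of a concentration index
#'
#' The decomposition reported one row per feature: the contribution of
#' feature `j` to inequality over a rank variable is
#' `D_j = I_j * CI_j`, the normalised feature importance times the
#' feature-specific concentration index. The same importance vector is
#' reused across rank variables; only the feature CIs change. Standard
#' errors of `D_j` treat `I_j` as fixed (`se(D_j) = I_j * se(CI_j)`);
#' bootstrap the full pipeline via [bootstrap_uncertainty()] for joint
#' uncertainty. Unlike the Shapley-rank decomposition, the product rule
#' carries no additivity guarantee, so the residual against a total CI is
#' reported, never hidden.
#'
#' @param importance An `"importance_result"`.
#' @param feature_cis Named list of `"concindex"` objects over the same
#'   features (order may differ; names must match).
#' @param rank_variable Name recorded on the rows.
#' @param total_ci Optional total concentration index (for example the
#'   model-predicted CI); when supplied, the sum of contributions and the
#'   residual `sum(D_j) - total` are attached.
#' @return Object of class `"ci_decomposition"`: data frame `rows` with
#'   feature, importance, feature CI (with se/bounds/stars) and
#'   contribution (with se/bounds/stars), plus `total_ci`, `sum_d`,
#'   `residual`.
#' @export
product_decomposition <- function(importance, feature_cis, rank_variable,
                                  total_ci = NULL) {
  stopifnot(inherits(importance, "importance_result"))
  if (!setequal(importance$feature, names(feature_cis)))
    stop("importance and feature CIs cover different feature sets",
         call. = FALSE)
  feature_cis <- feature_cis[importance$feature]
  I_j <- importance$normalized
  ci_j <- vapply(feature_cis, `[[`, numeric(1), "ci")
  se_j <- vapply(feature_cis, `[[`, numeric(1), "se")
  p_j <- vapply(feature_cis, function(x)
    if (is.na(x$p_value)) NA_real_ else x$p_value, numeric(1))
  d_j <- I_j * ci_j
  d_se <- I_j * se_j
  z <- stats::qnorm(1 - (1 - feature_cis[[1]]$conf) / 2)
  rows <- data.frame(
    rank_variable = rank_variable,
    feature = importance$feature,
    importance = I_j,
    feature_ci = unname(ci_j),
    feature_ci_se = unname(se_j),
    feature_ci_lower = unname(ci_j - z * se_j),
    feature_ci_upper = unname(ci_j + z * se_j),
    feature_ci_stars = vapply(p_j, .stars, ""),
    contribution = unname(d_j),
    contribution_se = unname(d_se),
    contribution_lower = unname(d_j - z * d_se),
    contribution_upper = unname(d_j + z * d_se),
    contribution_stars = vapply(p_j, .stars, ""),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(rows = rows, rank_variable = rank_variable,
         total_ci = total_ci, sum_d = sum(d_j),
         residual = if (is.null(total_ci)) NA_real_
         else sum(d_j) - total_ci),
    class = "ci_decomposition"
  )
}

#' @export
print.ci_decomposition <- function(x, digits = 3, ...) {
  cat(sprintf("Product-rule CI decomposition by %s\n", x$rank_variable))
  d <- x$rows[, c("feature", "importance", "feature_ci", "feature_ci_se",
                  "contribution", "contribution_stars")]
  d$importance <- round(d$importance, digits)
  d$feature_ci <- round(d$feature_ci, digits)
  d$feature_ci_se <- round(d$feature_ci_se, 4)
  d$contribution <- round(d$contribution, digits)
  print(d, row.names = FALSE)
  cat(sprintf("sum of contributions: %.4f", x$sum_d))
  if (!is.null(x$total_ci))
    cat(sprintf("; total CI %.4f; residual %.4f", x$total_ci, x$residual))
  cat("\n")
  invisible(x)
}

#' Shapley-rank decomposition of the predicted-probability CI
#'
#' Decomposes the concentration index of model predictions into exactly
#' additive per-feature terms: `c_j = 2 cov_w(phi_j, R) / mu` where
#' `phi_j` is feature `j`'s SHAP contribution column, `R` the fractional
#' ranks and `mu` the weighted mean prediction. Because local accuracy
#' makes the prediction the base value plus the sum of contributions, and
#' the covariance is linear in its first argument, the contributions sum
#' to the CI of the predictions exactly (the constant base value
#' contributes nothing). Decomposition is refused if local accuracy does
#' not hold.
#'
#' @param shap A `"shap_matrix"` for the records being decomposed.
#' @param R A [fractional_rank()] object over the same records.
#' @param predictions The model predictions for those records (defaults to
#'   the predictions stored in `shap`).
#' @param tol Local-accuracy tolerance (default 1e-6).
#' @return Object of class `"shap_rank_decomposition"`: `contributions`
#'   (named per-feature vector), `total_ci` (CI of predictions),
#'   `residual`, `rank_variable`.
#' @export
shap_rank_decomposition <- function(shap, R, predictions = NULL,
                                    tol = 1e-6) {
  stopifnot(inherits(shap, "shap_matrix"),
            inherits(R, "fractional_ranks"))
  if (is.null(predictions)) predictions <- shap$predictions
  if (length(predictions) != nrow(shap$phi) ||
      length(R$R) != nrow(shap$phi))
    stop("records of shap, ranks and predictions differ", call. = FALSE)
  resid_la <- abs(shap$base_value + rowSums(shap$phi) - predictions)
  if (max(resid_la) > tol)
    stop(sprintf(
      "local accuracy violated (max residual %.3g > %.1g): refusing to decompose",
      max(resid_la), tol), call. = FALSE)
  mu <- .wmean(predictions, R$w)
  if (mu == 0) stop("mean prediction is zero; CI undefined", call. = FALSE)
  contributions <- apply(shap$phi, 2L, function(col)
    2 * .wcov(col, R$R, R$w) / mu)
  total <- 2 * .wcov(predictions, R$R, R$w) / mu
  structure(
    list(contributions = contributions, total_ci = total,
         residual = sum(contributions) - total,
         rank_variable = R$spec$rank_variable),
    class = "shap_rank_decomposition"
  )
}

#' @export
print.shap_rank_decomposition <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Shapley-rank CI decomposition by %s (total CI %.4f, residual %.2g)\n",
    x$rank_variable, x$total_ci, x$residual))
  print(round(sort(x$contributions), digits))
  invisible(x)
}

#' Nonparametric bootstrap uncertainty for a pipeline statistic
#'
#' Resamples survey records with replacement (weights travel with their
#' records), re-evaluates a statistic on each replicate, and reports the
#' bootstrap standard error and percentile bounds. Replicates in which the
#' statistic fails (for example a degenerate resample) are dropped and
#' counted.
#'
#' @param statistic Function of a resampled table returning a numeric
#'   vector (scalar or named).
#' @param data Data frame (for example a `"survey_table"`) to resample.
#' @param B Number of bootstrap replicates (at least 100).
#' @param seed Integer seed.
#' @param conf Confidence level for the percentile bounds.
#' @return List with `estimate` (statistic on the original data), `se`,
#'   `lower`, `upper` (per component), `n_failed`, `B`.
#' @export
bootstrap_uncertainty <- function(statistic, data, B = 200L, seed = 1L,
                                  conf = 0.95) {
  if (B < 100L) stop("'B' must be at least 100", call. = FALSE)
  est <- statistic(data)
  set.seed(seed)
  reps <- vector("list", B)
  n_failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(nrow(data), replace = TRUE)
    reps[[b]] <- tryCatch(statistic(data[idx, , drop = FALSE]),
                          error = function(e) NULL)
    if (is.null(reps[[b]])) n_failed <- n_failed + 1L
  }
  mat <- do.call(rbind, Filter(Negate(is.null), reps))
  alpha <- (1 - conf) / 2
  list(
    estimate = est,
    se = apply(mat, 2L, stats::sd),
    lower = apply(mat, 2L, stats::quantile, probs = alpha, names = FALSE),
    upper = apply(mat, 2L, stats::quantile, probs = 1 - alpha,
                  names = FALSE),
    n_failed = n_failed, B = as.integer(B)
  )
}

#' Round half away from zero
#'
#' Reporting convention for decomposition tables: 3 decimals by default,
#' 4 where a published table prints 4; ties rounded away from zero rather
#' than to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 3L) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
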