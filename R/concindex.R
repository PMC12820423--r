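#' Rank-variable specification
#'
#' Defines how a rank variable orders the population from most
#' disadvantaged to most advantaged. Defaults: wealth quintile ascending
#' 1..5; education level ascending 0..3; ethnicity ordered tribe, then
#' no-caste/don't-know, then caste, so that a negative concentration index
#' means concentration among marginalised groups.
#'
#' @param rank_variable `"wealth_quintile"`, `"education_level"` or
#'   `"ethnicity"` (any other name is allowed with an explicit `ordering`).
#' @param ordering Optional vector of levels, most disadvantaged first;
#'   overrides the default.
#' @return Object of class `"rank_spec"`.
#' @export
rank_spec <- function(rank_variable, ordering = NULL) {
  if (is.null(ordering)) {
    ordering <- switch(
      rank_variable,
      wealth_quintile = 1:5,
      education_level = 0:3,
      ethnicity = c("tribe", "no_caste", "dont_know", "caste"),
      stop("no default ordering for '", rank_variable,
           "'; supply 'ordering'", call. = FALSE)
    )
  }
  if (anyDuplicated(ordering))
    stop("'ordering' must list each level once", call. = FALSE)
  structure(list(rank_variable = rank_variable, ordering = ordering,
                 tie_rule = "shared-midrank"),
            class = "rank_spec")
}

#' Weighted fractional ranks
#'
#' Sorts records by the rank variable and assigns each the weighted
#' fractional rank `(cumulative weight before + own weight / 2) / total`;
#' records tied at the same level all share the weighted mid-rank of their
#' tied group. The weighted mean of the ranks is exactly one half.
#'
#' @param values Rank-variable values (levels listed in `spec$ordering`).
#' @param w Positive weights.
#' @param spec A [rank_spec()].
#' @return Object of class `"fractional_ranks"`: `R` (ranks in input
#'   order), `w`, `group` (ordered level index per record), `spec`.
#' @examples
#' fr <- fractional_rank(c(1, 1, 2), rep(1, 3), rank_spec("g", 1:2))
#' fr$R  # 1/3, 1/3, 5/6
#' @export
fractional_rank <- function(values, w, spec) {
  stopifnot(inherits(spec, "rank_spec"))
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  g <- match(as.character(values), as.character(spec$ordering))
  if (anyNA(g))
    stop("unknown level(s): ",
         paste(unique(values[is.na(g)]), collapse = ", "), call. = FALSE)
  W <- sum(w)
  gw <- vapply(seq_along(spec$ordering),
               function(k) sum(w[g == k]), numeric(1))
  cum_before <- c(0, cumsum(gw))[seq_along(gw)]
  level_rank <- (cum_before + gw / 2) / W
  structure(list(R = level_rank[g], w = w, group = g, spec = spec),
            class = "fractional_ranks")
}

# Weighted covariance and variance with sum(w) normalisation.
.wcov <- function(x, y, w) {
  W <- sum(w)
  mx <- sum(w * x) / W
  my <- sum(w * y) / W
  sum(w * (x - mx) * (y - my)) / W
}
.wmean <- function(x, w) sum(w * x) / sum(w)

#' Concentration index (covariance form)
#'
#' `CI = 2 cov_w(y, R) / mu` where `R` are weighted fractional ranks and
#' `mu` the weighted mean of `y`. Positive values mean the quantity is
#' concentrated among the advantaged (pro-rich); negative among the
#' disadvantaged.
#'
#' @param y Numeric outcome (binary or continuous), weighted mean nonzero.
#' @param R A [fractional_rank()] object.
#' @return Scalar concentration index.
#' @export
concentration_index <- function(y, R) {
  stopifnot(inherits(R, "fractional_ranks"))
  mu <- .wmean(y, R$w)
  if (mu == 0) stop("weighted mean of 'y' is zero; CI undefined",
                    call. = FALSE)
  2 * .wcov(y, R$R, R$w) / mu
}

.stars <- function(p) {
  if (is.na(p)) "" else if (p < 0.001) "***" else if (p < 0.05) "**"
  else if (p < 0.1) "*" else ""
}

#' Concentration index by convenient regression
#'
#' Weighted least-squares regression of `2 sigma_R^2 (y_i / mu)` on the
#' fractional rank `R_i`: the slope equals the covariance-form
#' concentration index exactly, and the regression supplies a
#' heteroskedasticity-robust (HC1) standard error and confidence bounds.
#'
#' @param y Numeric outcome with nonzero weighted mean.
#' @param R A [fractional_rank()] object (n >= 3).
#' @param conf Confidence level for the bounds (default 0.95).
#' @param method Tag recorded on the result (default
#'   `"observed-conventional"`).
#' @return Object of class `"concindex"`: `ci`, `se`, `lower`, `upper`,
#'   `conf`, `p_value`, `stars`, `method`, `rank_variable`, `n`, `mu`.
#' @export
ci_convenient_regression <- function(y, R, conf = 0.95,
                                     method = "observed-conventional") {
  stopifnot(inherits(R, "fractional_ranks"))
  n <- length(y)
  if (n < 3L) stop("need at least 3 records", call. = FALSE)
  mu <- .wmean(y, R$w)
  if (mu == 0) stop("weighted mean of 'y' is zero; CI undefined",
                    call. = FALSE)
  var_R <- .wcov(R$R, R$R, R$w)
  if (var_R <= 0)
    stop("degenerate ranks: no variation in the rank variable",
         call. = FALSE)
  lhs <- 2 * var_R * y / mu
  fit <- stats::lm(lhs ~ rank, data = data.frame(lhs = lhs, rank = R$R),
                   weights = R$w)
  ci <- unname(stats::coef(fit)["rank"])
  # sandwich's bread() consults summary.lm, which warns on an exactly
  # collinear outcome (e.g. the rank variable's own feature CI); the SE
  # is a clean zero there
  se <- suppressWarnings(
    sqrt(sandwich::vcovHC(fit, type = "HC1")["rank", "rank"]))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- 2 * stats::pnorm(-abs(ci / se))
  structure(
    list(ci = ci, se = se, lower = ci - z * se, upper = ci + z * se,
         conf = conf, p_value = p, stars = .stars(p), method = method,
         rank_variable = R$spec$rank_variable, n = n, mu = mu),
    class = "concindex"
  )
}

#' @export
print.concindex <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Concentration index (%s) by %s: %.*f%s  SE %.*f  %d%% CI [%.*f, %.*f]  (n = %d, mu = %.4g)\n",
    x$method, x$rank_variable, digits, x$ci, x$stars, digits, x$se,
    round(100 * x$conf), digits, x$lower, digits, x$upper, x$n, x$mu))
  invisible(x)
}

#' @export
confint.concindex <- function(object, parm, level = NULL, ...) {
  if (!is.null(level) && level != object$conf) {
    z <- stats::qnorm(1 - (1 - level) / 2)
    return(c(object$ci - z * object$se, object$ci + z * object$se))
  }
  c(object$lower, object$upper)
}

#' Erreygers-corrected concentration index
#'
#' For a bounded outcome on `[0, 1]` (in particular binary screening
#' uptake) the standard concentration index has a mean-dependent
#' attainable range; the Erreygers correction `E = 4 mu CI` removes that
#' dependence. Offered as an option; the default reporting keeps plain
#' concentration indices.
#'
#' @param x A `"concindex"` (with its weighted mean `mu` recorded).
#' @return A `"concindex"` with index, SE and bounds multiplied by
#'   `4 mu` and method suffixed `"-erreygers"`.
#' @export
erreygers_index <- function(x) {
  stopifnot(inherits(x, "concindex"))
  if (is.na(x$mu)) stop("'mu' not recorded; cannot correct", call. = FALSE)
  k <- 4 * x$mu
  x$ci <- k * x$ci
  x$se <- k * x$se
  x$lower <- k * x$lower
  x$upper <- k * x$upper
  x$method <- paste0(x$method, "-erreygers")
  x
}

#' Concentration index of model-predicted probabilities
#'
#' Applies a fitted classifier to the data, ranks records by the rank
#' variable and computes the concentration index of the predicted event
#' probabilities, with SE and bounds from the convenient regression. This
#' is the algorithm-based counterpart of the conventional observed-outcome
#' index.
#'
#' @param model An `"uptake_model"`.
#' @param data An `"encoded_matrix"` containing the rank variable.
#' @param spec A [rank_spec()].
#' @param conf Confidence level.
#' @return A `"concindex"` with method `"model-predicted"`.
#' @export
ci_from_predictions <- function(model, data, spec, conf = 0.95) {
  stopifnot(inherits(data, "encoded_matrix"), inherits(spec, "rank_spec"))
  preds <- predict(model, data)
  vals <- .rank_values(data, spec$rank_variable, levels = spec$ordering)
  R <- fractional_rank(vals, data$w, spec)
  ci_convenient_regression(preds, R, conf = conf,
                           method = "model-predicted")
}

# Recover a rank variable's per-record level from an encoded matrix.
# Ordinal values are snapped to the nearest level of `levels` (when given)
# so interpolated synthetic records remain rankable.
.rank_values <- function(data, rank_variable, levels = NULL) {
  m <- data$encoding_map[[rank_variable]]
  if (is.null(m))
    stop("rank variable '", rank_variable, "' not in encoded data",
         call. = FALSE)
  if (m$type == "onehot") {
    block <- data$X[, m$columns, drop = FALSE]
    m$levels[max.col(block, ties.method = "first")]
  } else {
    v <- data$X[, m$columns]
    if (!is.null(levels) && is.numeric(utils::type.convert(as.character(levels),
                                                          as.is = TRUE))) {
      lv <- as.numeric(levels)
      v <- lv[vapply(v, function(x) which.min(abs(lv - x)), 1L)]
    }
    v
  }
}

#' Pearson chi-squared test of independence
#'
#' @param counts An `r x c` matrix of nonnegative counts with at least two
#'   rows and two columns and no all-zero row or column.
#' @return List with `chi2` (Pearson statistic, no continuity correction),
#'   `df = (r-1)(c-1)` and the upper-tail `p` value.
#' @examples
#' chi2_independence(matrix(c(20, 10, 10, 20), 2))
#' @export
chi2_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("need at least a 2 x 2 table", call. = FALSE)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal row or column", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Weighted bivariate association table
#'
#' Cross-tabulates a categorical factor against the binary outcome using
#' survey weights (weighted counts) and runs the chi-squared test of
#' independence on the weighted table, as in descriptive bivariate
#' screening-uptake profiles.
#'
#' @param table A `"survey_table"`.
#' @param var Name of the categorical/ordinal column.
#' @param weighted Use survey weights (default TRUE).
#' @return Data frame with one row per level: weighted count, share,
#'   weighted screened count, screened percent; attributes `chi2`, `df`,
#'   `p`.
#' @export
bivariate_association <- function(table, var, weighted = TRUE) {
  v <- table[[var]]
  if (is.null(v)) stop("no column '", var, "'", call. = FALSE)
  w <- if (weighted) table$w else rep(1, nrow(table))
  lev <- if (is.factor(v)) levels(v) else sort(unique(v))
  n_lev <- vapply(lev, function(l) sum(w[v == l]), 1)
  n_pos <- vapply(lev, function(l) sum(w[v == l & table$y == 1]), 1)
  tab2 <- cbind(screened = n_pos, not = n_lev - n_pos)
  ht <- chi2_independence(tab2)
  out <- data.frame(
    variable = var, level = as.character(lev),
    n = n_lev, share = n_lev / sum(n_lev),
    screened = n_pos, screened_pct = 100 * n_pos / n_lev,
    row.names = NULL
  )
  attr(out, "chi2") <- ht$chi2
  attr(out, "df") <- ht$df
  attr(out, "p") <- ht$p
  out
}
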