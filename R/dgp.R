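# Canonical variable sets for the generator and downstream encoding.
.rank_vars <- c("wealth_quintile", "education_level", "ethnicity")

.access_vars <- c(
  "met_chw", "chw_type", "female_provider_unavailable", "autonomy_index",
  "hesitancy", "safe_water", "sanitation", "distance_problem",
  "transport_problem", "insurance", "money_for_treatment", "occupation",
  "services_discussed", "pqc_index"
)

.base_vars <- c("wealth_quintile", "education_level", "ethnicity")

.demo_vars <- c("age_group", "state", "residence")

.ethnicity_levels <- c("caste", "tribe", "no_caste", "dont_know")

# Marginal prevalence and loading direction on the latent socioeconomic
# score for each threshold-generated access item. Positive direction means
# the item is more common among wealthier/more educated women.
.access_items <- list(
  met_chw                     = list(prev = 0.40, dir = +1),
  services_discussed          = list(prev = 0.30, dir = +1),
  female_provider_unavailable = list(prev = 0.20, dir = -1),
  hesitancy                   = list(prev = 0.35, dir = -1),
  safe_water                  = list(prev = 0.90, dir = +1),
  sanitation                  = list(prev = 0.70, dir = +1),
  distance_problem            = list(prev = 0.40, dir = -1),
  transport_problem           = list(prev = 0.25, dir = -1),
  insurance                   = list(prev = 0.30, dir = +1),
  money_for_treatment         = list(prev = 0.45, dir = -1),
  occupation                  = list(prev = 0.25, dir = -1),
  autonomy_perm_self          = list(prev = 0.60, dir = +1),
  autonomy_perm_birth         = list(prev = 0.60, dir = +1),
  pqc_timing                  = list(prev = 0.65, dir = +1),
  pqc_staff                   = list(prev = 0.65, dir = +1),
  pqc_wait                    = list(prev = 0.65, dir = +1),
  pqc_quality                 = list(prev = 0.65, dir = +1)
)

# Coefficient names accepted by the data-generating process.
.coef_names <- c(
  "wealth_quintile", "education_level", "age_group", "residence", "state",
  paste0("ethnicity_", .ethnicity_levels[-1]),
  .access_vars
)

#' Configuration of the synthetic survey data-generating process
#'
#' Bundles everything that defines the generator: sample size, seed, the
#' logistic outcome model (intercept and named logit-scale coefficients),
#' marginal shares of the three rank variables, the number of states, the
#' strength of the mediation pathway linking access covariates to
#' wealth/education, and the dispersion of the survey weights.
#'
#' The outcome follows `Pr(y = 1 | x) = plogis(intercept + sum_j coef_j x_j)`
#' where ordinal covariates enter as integer scores, binary covariates as
#' 0/1, `state` scales a vector of per-state normal offsets, and ethnicity
#' contrasts (`ethnicity_tribe`, `ethnicity_no_caste`, `ethnicity_dont_know`)
#' are offsets relative to the caste reference level.
#'
#' @param n_records Number of records to generate (positive integer).
#' @param seed Integer seed; identical configurations reproduce identical
#'   tables byte for byte.
#' @param intercept Intercept of the outcome logit.
#' @param coef Named numeric vector of logit-scale effects. Names must be
#'   drawn from the generator's coefficient vocabulary (see Details); an
#'   unknown name is an error. An empty vector gives the null model.
#' @param wealth_shares,education_shares,caste_shares Marginal shares of the
#'   five wealth quintiles, four education levels and four ethnicity
#'   categories (caste, tribe, no caste, don't know). Each must sum to 1.
#' @param n_states Number of states (uniform shares, normal outcome offsets
#'   with standard deviation `state_sd`).
#' @param mediation_strength Correlation, in `[0, 1]`, between each access
#'   covariate's latent propensity and the latent socioeconomic score that
#'   drives wealth and education. Zero makes access covariates independent
#'   of socioeconomic position.
#' @param weight_dispersion Log-scale standard deviation of the lognormal
#'   survey weights (normalised to mean 1); 0 gives equal weights.
#' @param wealth_education_rho Gaussian-copula correlation between the
#'   wealth and education marginals.
#' @param state_sd Standard deviation of the per-state outcome offsets.
#' @return An object of class `"dgp_config"`.
#' @seealso [generate_survey()], [nfhs_like_preset()], [implied_ci()]
#' @export
dgp_config <- function(n_records,
                       seed = 1L,
                       intercept = stats::qlogis(0.005),
                       coef = numeric(0),
                       wealth_shares = rep(0.2, 5),
                       education_shares = rep(0.25, 4),
                       caste_shares = rep(0.25, 4),
                       n_states = 20L,
                       mediation_strength = 0.5,
                       weight_dispersion = 0.5,
                       wealth_education_rho = 0.5,
                       state_sd = 0.3) {
  n_records <- as.integer(n_records)
  if (is.na(n_records) || n_records < 1L)
    stop("'n_records' must be a positive integer", call. = FALSE)
  check_shares <- function(x, k, what) {
    if (length(x) != k)
      stop(sprintf("'%s' must have %d entries", what, k), call. = FALSE)
    if (any(x < 0) || abs(sum(x) - 1) > 1e-9)
      stop(sprintf("'%s' must be nonnegative and sum to 1", what),
           call. = FALSE)
    x
  }
  check_shares(wealth_shares, 5L, "wealth_shares")
  check_shares(education_shares, 4L, "education_shares")
  check_shares(caste_shares, 4L, "caste_shares")
  if (length(coef)) {
    if (is.null(names(coef)) || any(!nzchar(names(coef))))
      stop("'coef' must be a named vector", call. = FALSE)
    unknown <- setdiff(names(coef), .coef_names)
    if (length(unknown))
      stop("unknown coefficient name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  if (mediation_strength < 0 || mediation_strength > 1)
    stop("'mediation_strength' must lie in [0, 1]", call. = FALSE)
  if (weight_dispersion < 0)
    stop("'weight_dispersion' must be nonnegative", call. = FALSE)
  structure(
    list(
      n_records = n_records, seed = as.integer(seed),
      intercept = intercept, coef = coef,
      wealth_shares = wealth_shares, education_shares = education_shares,
      caste_shares = caste_shares, n_states = as.integer(n_states),
      mediation_strength = mediation_strength,
      weight_dispersion = weight_dispersion,
      wealth_education_rho = wealth_education_rho,
      state_sd = state_sd
    ),
    class = "dgp_config"
  )
}

#' @export
print.dgp_config <- function(x, ...) {
  cat("Synthetic survey DGP configuration\n")
  cat(sprintf("  records: %d, seed: %d, states: %d\n",
              x$n_records, x$seed, x$n_states))
  cat(sprintf("  intercept (logit): %.4f; %d nonzero coefficient(s)\n",
              x$intercept, sum(x$coef != 0)))
  cat(sprintf("  mediation strength: %.2f, weight dispersion: %.2f\n",
              x$mediation_strength, x$weight_dispersion))
  invisible(x)
}

# Draw an ordinal variable with given marginal shares from a standard
# normal latent value (Gaussian copula): exact margins, tunable dependence.
.cut_latent <- function(z, shares, scores) {
  br <- stats::qnorm(cumsum(shares)[-length(shares)])
  scores[findInterval(z, br) + 1L]
}

#' Generate a synthetic NFHS-like survey table
#'
#' Draws a per-woman survey table from the logistic data-generating process
#' described in [dgp_config()]. Wealth quintile and education level are
#' coupled through a Gaussian copula so their printed marginal shares are
#' exact while remaining correlated; binary access covariates are generated
#' by thresholding a latent mix of the socioeconomic score and independent
#' noise, so `mediation_strength` controls how strongly access tracks
#' socioeconomic position. The health-seeking autonomy and perceived
#' quality-of-care (PQC) indices are sum scores of their generated items.
#' Survey weights are lognormal, normalised to mean 1, and independent of
#' the covariates.
#'
#' @param config A [dgp_config()] object.
#' @return A `data.frame` of class `"survey_table"` with one row per woman:
#'   outcome `y`, rank variables (`wealth_quintile` 1..5, `education_level`
#'   0..3, `ethnicity`), demographics (`age_group`, `state`, `residence`),
#'   the raw autonomy/PQC items, the fourteen access covariates, and survey
#'   weight `w`. The true event probabilities are attached as attribute
#'   `"true_p"` and the configuration as `"config"`.
#' @examples
#' tab <- generate_survey(dgp_config(500, seed = 7))
#' mean(tab$y)
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "dgp_config"))
  n <- config$n_records
  set.seed(config$seed)

  state_offsets <- stats::rnorm(config$n_states, 0, config$state_sd)

  rho <- config$wealth_education_rho
  z_w <- stats::rnorm(n)
  z_e <- rho * z_w + sqrt(1 - rho^2) * stats::rnorm(n)
  wealth_quintile <- .cut_latent(z_w, config$wealth_shares, 1:5)
  education_level <- .cut_latent(z_e, config$education_shares, 0:3)

  # Latent socioeconomic score driving the mediation pathway (std normal).
  ses <- (z_w + z_e) / sqrt(2 + 2 * rho)

  ethnicity <- factor(
    sample(.ethnicity_levels, n, replace = TRUE, prob = config$caste_shares),
    levels = .ethnicity_levels
  )
  age_group <- sample(1:4, n, replace = TRUE)
  state <- factor(
    sprintf("S%02d", sample(seq_len(config$n_states), n, replace = TRUE)),
    levels = sprintf("S%02d", seq_len(config$n_states))
  )
  residence <- as.integer(
    stats::runif(n) < stats::plogis(-0.8 + 0.4 * (wealth_quintile - 3))
  )

  m <- config$mediation_strength
  items <- list()
  for (nm in names(.access_items)) {
    spec <- .access_items[[nm]]
    latent <- spec$dir * m * ses + sqrt(1 - m^2) * stats::rnorm(n)
    items[[nm]] <- as.integer(latent > stats::qnorm(1 - spec$prev))
  }
  chw_type <- ifelse(
    items$met_chw == 1L,
    sample(1:3, n, replace = TRUE, prob = c(0.6, 0.3, 0.1)),
    0L
  )

  tab <- data.frame(
    wealth_quintile = wealth_quintile,
    education_level = education_level,
    ethnicity = ethnicity,
    age_group = age_group,
    state = state,
    residence = residence,
    autonomy_perm_self = items$autonomy_perm_self,
    autonomy_perm_birth = items$autonomy_perm_birth,
    pqc_timing = items$pqc_timing,
    pqc_staff = items$pqc_staff,
    pqc_wait = items$pqc_wait,
    pqc_quality = items$pqc_quality,
    met_chw = items$met_chw,
    chw_type = as.integer(chw_type),
    female_provider_unavailable = items$female_provider_unavailable,
    hesitancy = items$hesitancy,
    safe_water = items$safe_water,
    sanitation = items$sanitation,
    distance_problem = items$distance_problem,
    transport_problem = items$transport_problem,
    insurance = items$insurance,
    money_for_treatment = items$money_for_treatment,
    occupation = items$occupation,
    services_discussed = items$services_discussed,
    stringsAsFactors = FALSE
  )
  tab$autonomy_index <- build_autonomy_index(
    tab[, c("autonomy_perm_self", "autonomy_perm_birth")]
  )
  tab$pqc_index <- build_pqc_index(
    tab[, c("pqc_timing", "pqc_staff", "pqc_wait", "pqc_quality")]
  )

  lp <- rep(config$intercept, n)
  cf <- config$coef
  for (nm in names(cf)) {
    lp <- lp + cf[[nm]] * switch(
      nm,
      state = state_offsets[as.integer(state)],
      ethnicity_tribe = as.numeric(ethnicity == "tribe"),
      ethnicity_no_caste = as.numeric(ethnicity == "no_caste"),
      ethnicity_dont_know = as.numeric(ethnicity == "dont_know"),
      tab[[nm]]
    )
  }
  p <- stats::plogis(lp)
  tab$y <- stats::rbinom(n, 1L, p)

  if (config$weight_dispersion > 0) {
    w <- stats::rlnorm(n, -config$weight_dispersion^2 / 2,
                       config$weight_dispersion)
  } else {
    w <- rep(1, n)
  }
  tab$w <- w / mean(w)

  stopifnot(!anyNA(tab), all(tab$w > 0))
  structure(tab, true_p = p, config = config,
            class = c("survey_table", "data.frame"))
}

#' @export
print.survey_table <- function(x, ...) {
  cat(sprintf(
    "Synthetic survey table: %d records, outcome prevalence %.3f%% (unweighted)\n",
    nrow(x), 100 * mean(x$y)))
  NextMethod()
}

#' NFHS-5-like generator preset
#'
#' A ready-made [dgp_config()] emulating the structure of the NFHS-5
#' (2019-21) sample of women aged 30-49 screened for breast cancer by
#' clinical breast examination: marginal wealth-quintile shares of
#' 29.19/20.60/16.73/16.27/17.21 percent, four education levels
#' (31.39/13.54/38.95/16.12), four ethnicity categories
#' (74.82/19.75/4.97/0.46), an overall outcome prevalence near 0.5 percent
#' rising from roughly 0.3 percent in the poorest quintile to roughly 0.75
#' percent in the richest, and access covariates that mediate part of the
#' socioeconomic gradient.
#'
#' @param n_records Number of records (default 50,000).
#' @param seed Integer seed.
#' @return A `"dgp_config"` object.
#' @export
nfhs_like_preset <- function(n_records = 50000L, seed = 1L) {
  dgp_config(
    n_records = n_records,
    seed = seed,
    intercept = -6.60,
    coef = c(
      wealth_quintile = 0.02,
      education_level = 0.22,
      age_group = 0.10,
      residence = 0.12,
      state = 1.0,
      ethnicity_tribe = -0.25,
      ethnicity_no_caste = -0.10,
      ethnicity_dont_know = 0.30,
      met_chw = 0.18,
      chw_type = 0.03,
      female_provider_unavailable = -0.08,
      autonomy_index = 0.15,
      hesitancy = -0.18,
      safe_water = 0.08,
      sanitation = 0.08,
      distance_problem = -0.15,
      transport_problem = -0.08,
      insurance = 0.05,
      money_for_treatment = -0.15,
      occupation = -0.03,
      services_discussed = 0.20,
      pqc_index = 0.06
    ),
    wealth_shares = c(0.2919, 0.2060, 0.1673, 0.1627, 0.1721),
    education_shares = c(0.3139, 0.1354, 0.3895, 0.1612),
    caste_shares = c(0.7482, 0.1975, 0.0497, 0.0046),
    n_states = 20L,
    mediation_strength = 0.5,
    weight_dispersion = 0.5
  )
}

#' Monte-Carlo concentration index implied by a generator configuration
#'
#' Estimates the concentration index of the true event probability
#' `Pr(y = 1 | x)` over a rank variable by drawing a large Monte-Carlo
#' sample from the data-generating process. This is the parameter-recovery
#' oracle against which sample concentration indices are compared: it uses
#' the generator's exact probabilities, not realised outcomes, so its only
#' error is Monte-Carlo.
#'
#' @param config A [dgp_config()] object.
#' @param rank_var One of `"wealth_quintile"`, `"education_level"`,
#'   `"ethnicity"`.
#' @param n_mc Monte-Carlo sample size (at least 1,000).
#' @param seed Seed for the Monte-Carlo draw (independent of
#'   `config$seed`).
#' @return A list with components `ci` (the Monte-Carlo estimate), `se`
#'   (batch-means standard error over 20 batches), `rank_variable` and
#'   `n_mc`.
#' @export
implied_ci <- function(config, rank_var, n_mc = 200000L, seed = 1L) {
  stopifnot(inherits(config, "dgp_config"))
  if (n_mc < 1000L)
    stop("'n_mc' must be at least 1,000 for a stable oracle", call. = FALSE)
  if (!rank_var %in% .rank_vars)
    stop("'rank_var' must be one of: ", paste(.rank_vars, collapse = ", "),
         call. = FALSE)
  cfg <- config
  cfg$n_records <- as.integer(n_mc)
  cfg$seed <- as.integer(seed)
  tab <- generate_survey(cfg)
  p <- attr(tab, "true_p")
  spec <- rank_spec(rank_var)
  ci_one <- function(idx) {
    R <- fractional_rank(tab[[rank_var]][idx], tab$w[idx], spec)
    concentration_index(p[idx], R)
  }
  ci <- ci_one(seq_len(nrow(tab)))
  n_batch <- 20L
  batch <- split(seq_len(nrow(tab)),
                 rep(seq_len(n_batch), length.out = nrow(tab)))
  batch_ci <- vapply(batch, ci_one, numeric(1))
  list(ci = ci, se = stats::sd(batch_ci) / sqrt(n_batch),
       rank_variable = rank_var, n_mc = as.integer(n_mc))
}

#' Write a survey table and its configuration to disk
#'
#' @param table A `"survey_table"`.
#' @param file Path of the CSV to write (header included).
#' @param config_file Optional path; when given, the generating
#'   configuration is archived alongside as JSON.
#' @return `file`, invisibly.
#' @export
write_survey_csv <- function(table, file, config_file = NULL) {
  utils::write.csv(as.data.frame(table), file, row.names = FALSE)
  if (!is.null(config_file)) {
    cfg <- attr(table, "config")
    if (!is.null(cfg))
      jsonlite::write_json(unclass(cfg), config_file, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
  }
  invisible(file)
}

#' Read a survey table from a CSV export
#'
#' Generic adapter for flat one-row-per-respondent CSV files (for example a
#' DHS flat export): requires a header, the outcome column `y`, a positive
#' weight column `w`, and whatever rank variables and covariates the
#' analysis will use. `ethnicity` and `state`, when present, are read as
#' factors.
#'
#' @param file Path to a CSV file with header.
#' @return A `"survey_table"` data frame.
#' @export
read_survey_csv <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("y", "w") %in% names(tab)))
    stop("survey CSV must contain columns 'y' and 'w'", call. = FALSE)
  if (any(tab$w <= 0)) stop("all weights must be positive", call. = FALSE)
  if (!all(tab$y %in% c(0, 1)))
    stop("'y' must be binary 0/1", call. = FALSE)
  if ("ethnicity" %in% names(tab)) {
    lev <- intersect(.ethnicity_levels, unique(tab$ethnicity))
    lev <- c(lev, setdiff(unique(tab$ethnicity), lev))
    tab$ethnicity <- factor(tab$ethnicity, levels = lev)
  }
  if ("state" %in% names(tab)) tab$state <- factor(tab$state)
  structure(tab, class = c("survey_table", "data.frame"))
}
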