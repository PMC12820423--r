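test_that("fractional ranks follow the weighted mid-rank formula", {
  spec <- rank_spec("g", ordering = 1:4)
  fr <- fractional_rank(1:4, rep(1, 4), spec)
  expect_equal(fr$R, c(0.125, 0.375, 0.625, 0.875))

  fr2 <- fractional_rank(c(1, 1, 2), rep(1, 3), rank_spec("g", 1:2))
  expect_equal(fr2$R, c(1 / 3, 1 / 3, 5 / 6))

  # weighted mean one half by construction, on random inputs
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    vals <- sample(1:5, n, replace = TRUE)
    w <- rexp(n) + 0.05
    fr3 <- fractional_rank(vals, w, rank_spec("wealth_quintile"))
    expect_equal(sum(fr3$R * w) / sum(w), 0.5, tolerance = 1e-9)
    # non-decreasing in the rank variable
    expect_true(all(diff(fr3$R[order(vals)]) >= -1e-12))
  }

  expect_error(fractional_rank(c(1, 9), c(1, 1), rank_spec("g", 1:5)),
               "unknown level")
  expect_error(fractional_rank(c(1, 2), c(1, -1), rank_spec("g", 1:5)),
               "positive")
})

test_that("concentration index matches direct covariance arithmetic", {
  spec <- rank_spec("g", 1:4)
  R <- fractional_rank(1:4, rep(1, 4), spec)
  expect_equal(concentration_index(c(0, 0, 1, 1), R), 0.5)
  expect_equal(concentration_index(rep(3, 4), R), 0)
  expect_error(concentration_index(rep(0, 4), R), "zero")

  # reversing the ordering flips the sign exactly
  Rrev <- fractional_rank(1:4, rep(1, 4), rank_spec("g", 4:1))
  expect_equal(concentration_index(c(0, 0, 1, 1), Rrev), -0.5)

  # invariant to uniform positive weight scaling
  set.seed(8)
  vals <- sample(1:5, 200, replace = TRUE)
  y <- rbinom(200, 1, 0.3 + 0.1 * (vals - 3) / 2)
  w <- rexp(200) + 0.1
  R1 <- fractional_rank(vals, w, rank_spec("wealth_quintile"))
  R2 <- fractional_rank(vals, 37 * w, rank_spec("wealth_quintile"))
  expect_equal(concentration_index(y, R1), concentration_index(y, R2),
               tolerance = 1e-12)
})

test_that("convenient regression slope equals the covariance form", {
  set.seed(21)
  for (rep in 1:25) {
    n <- 300
    vals <- sample(1:5, n, replace = TRUE)
    w <- rlnorm(n, 0, 0.6)
    y <- rbinom(n, 1, plogis(-1 + 0.4 * vals))
    if (mean(y) == 0) next
    R <- fractional_rank(vals, w, rank_spec("wealth_quintile"))
    res <- ci_convenient_regression(y, R)
    expect_equal(res$ci, concentration_index(y, R), tolerance = 1e-10)
    expect_true(res$lower <= res$ci && res$ci <= res$upper)
    expect_gte(res$se, 0)
  }
  R4 <- fractional_rank(c(1, 1, 2, 2), rep(1, 4), rank_spec("g", 1:2))
  toy <- ci_convenient_regression(c(0, 0, 1, 1), R4)
  expect_equal(toy$ci, 0.5, tolerance = 1e-12)
})

test_that("regression SE is consistent with a bootstrap of the CI", {
  set.seed(33)
  n <- 1000
  vals <- sample(1:5, n, replace = TRUE)
  w <- rlnorm(n, 0, 0.5)
  y <- rbinom(n, 1, plogis(-2 + 0.45 * vals))
  d <- data.frame(vals = vals, w = w, y = y)
  R <- fractional_rank(d$vals, d$w, rank_spec("wealth_quintile"))
  res <- ci_convenient_regression(d$y, R)
  boot <- bootstrap_uncertainty(function(dd) {
    RR <- fractional_rank(dd$vals, dd$w, rank_spec("wealth_quintile"))
    concentration_index(dd$y, RR)
  }, d, B = 1000, seed = 5)
  expect_lt(abs(res$se - boot$se) / boot$se, 0.20)
})

test_that("prediction-based CI behaves like the observed CI in limits", {
  tab <- generate_survey(dgp_config(800, seed = 41,
                                    intercept = qlogis(0.2),
                                    coef = c(wealth_quintile = 0.5)))
  enc <- encode_features(tab)
  spec <- rank_spec("wealth_quintile")

  const <- toy_linear_model(rep(0, ncol(enc$X)), intercept = 0.4,
                            feature_names = colnames(enc$X))
  const$encoding_map <- enc$encoding_map
  expect_equal(ci_from_predictions(const, enc, spec)$ci, 0,
               tolerance = 1e-12)

  # oracle predictor reproducing y exactly gives the observed CI
  enc2 <- enc
  enc2$X <- cbind(enc$X, yhat = as.numeric(enc$y))
  enc2$feature_names <- c(enc$feature_names, "yhat")
  enc2$encoding_map$yhat <- list(type = "ordinal",
                                 columns = ncol(enc2$X), base = FALSE)
  oracle <- toy_linear_model(c(rep(0, ncol(enc$X)), 1),
                             feature_names = colnames(enc2$X))
  oracle$encoding_map <- enc2$encoding_map
  R <- fractional_rank(tab$wealth_quintile, tab$w, spec)
  expect_equal(ci_from_predictions(oracle, enc2, spec)$ci,
               concentration_index(tab$y, R), tolerance = 1e-10)
})

test_that("predicted and observed CIs share a sign on preset data", {
  tab <- generate_survey(nfhs_like_preset(20000, seed = 19))
  enc <- encode_features(tab)
  bal <- smote_oversample(enc, seed = 19)
  plan <- make_splits(bal, 0.8, 5, seed = 19)
  model <- fit_model("decision-tree", slice_records(bal, plan$train_idx),
                     seed = 19)
  for (rv in c("wealth_quintile", "education_level")) {
    spec <- rank_spec(rv)
    obs <- concentration_index(
      tab$y, fractional_rank(tab[[rv]], tab$w, spec))
    prd <- ci_from_predictions(model, enc, spec)$ci
    expect_gt(obs * prd, 0)
  }
})

test_that("binary-outcome CI respects the attainable-bound property", {
  set.seed(55)
  for (rep in 1:10) {
    n <- 500
    vals <- sample(1:5, n, replace = TRUE)
    w <- rlnorm(n, 0, 0.4)
    y <- rbinom(n, 1, plogis(-2.5 + 0.8 * vals))
    if (sum(y) == 0) next
    R <- fractional_rank(vals, w, rank_spec("wealth_quintile"))
    ci <- concentration_index(y, R)
    mu <- sum(w * y) / sum(w)
    expect_lte(abs(ci), 1 - mu + 0.01)
  }
})

test_that("Erreygers correction rescales by four times the mean", {
  R <- fractional_rank(1:4, rep(1, 4), rank_spec("g", 1:4))
  res <- ci_convenient_regression(c(0, 0, 1, 1), R)
  e <- erreygers_index(res)
  expect_equal(e$ci, 4 * 0.5 * res$ci)
  expect_equal(e$se, 4 * 0.5 * res$se)
  expect_match(e$method, "erreygers")
})

test_that("chi-squared independence test matches closed forms", {
  uni <- matrix(25, 2, 2)
  res <- chi2_independence(uni)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)

  res2 <- chi2_independence(matrix(c(20, 10, 10, 20), 2))
  # n (ad - bc)^2 / (r1 r2 c1 c2)
  expect_equal(res2$chi2, 60 * (20 * 20 - 10 * 10)^2 / 30^4)
  expect_equal(res2$chi2, 20 / 3, tolerance = 1e-12)
  expect_equal(res2$df, 1)

  # 5x2 expected-count arithmetic on a hand-checked toy
  tab <- cbind(c(10, 20, 30, 20, 20), c(90, 80, 70, 80, 80))
  exp_first <- sum(tab[1, ]) * sum(tab[, 1]) / sum(tab)
  manual <- sum((tab - outer(rowSums(tab), colSums(tab)) / sum(tab))^2 /
                  (outer(rowSums(tab), colSums(tab)) / sum(tab)))
  res3 <- chi2_independence(tab)
  expect_equal(res3$chi2, manual)
  expect_equal(res3$df, 4)
  expect_equal(exp_first, 100 * 100 / 500)

  expect_error(chi2_independence(matrix(c(1, 2), 1)), "2 x 2")
  expect_error(chi2_independence(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("bivariate association reproduces weighted group shares", {
  tab <- generate_survey(nfhs_like_preset(5000, seed = 23))
  a <- bivariate_association(tab, "wealth_quintile")
  expect_equal(nrow(a), 5)
  expect_equal(sum(a$share), 1, tolerance = 1e-12)
  expect_equal(sum(a$n), sum(tab$w), tolerance = 1e-9)
  expect_true(is.finite(attr(a, "chi2")))
  expect_equal(attr(a, "df"), 4)
})
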