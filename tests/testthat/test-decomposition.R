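test_that("feature CI tracks the feature's relationship to rank", {
  spec <- rank_spec("g", 1:6)
  R <- fractional_rank(1:6, rep(1, 6), spec)

  # feature equal to the rank score: strongly positive CI
  self_ci <- feature_ci(1:6, R)
  expect_gt(self_ci$ci, 0.2)

  # binary feature concentrated among low ranks: negative CI, by hand:
  # y = (1,1,1,0,0,0), mu = .5, ranks (1..6 - .5)/6
  low <- feature_ci(c(1, 1, 1, 0, 0, 0), R)
  ranks <- ((1:6) - 0.5) / 6
  hand <- 2 * mean((c(1, 1, 1, 0, 0, 0) - 0.5) * (ranks - 0.5)) / 0.5
  expect_equal(low$ci, hand, tolerance = 1e-12)
  expect_lt(low$ci, 0)

  # feature independent of rank on a larger draw
  set.seed(71)
  vals <- sample(1:5, 4000, replace = TRUE)
  noise <- rbinom(4000, 1, 0.5)
  Rbig <- fractional_rank(vals, rep(1, 4000), rank_spec("wealth_quintile"))
  expect_lt(abs(feature_ci(noise, Rbig)$ci), 0.05)
})

test_that("nonpositive-mean features are shifted or refused", {
  spec <- rank_spec("g", 1:4)
  R <- fractional_rank(1:4, rep(1, 4), spec)
  centred <- c(-1, -1, 1, 1)
  res <- feature_ci(centred, R)
  expect_true(attr(res, "shifted"))
  # after +1 shift values are (0,0,2,2), mu = 1: CI = 2 cov / 1
  expect_equal(res$ci, 2 * mean((c(0, 0, 2, 2) - 1) *
                                  (c(0.125, 0.375, 0.625, 0.875) - 0.5)),
               tolerance = 1e-12)
  expect_error(feature_ci(centred, R, shift_nonpositive = FALSE),
               "nonpositive")
  # constant features yield an exact zero with no variance
  cst <- feature_ci(rep(2, 4), R)
  expect_equal(cst$ci, 0)
  expect_equal(cst$se, 0)
})

test_that("product rule reproduces the published worked examples", {
  imp <- screenineq:::.importance_result(
    c("economic", "autonomy"), c(0.055, 0.089), "shap-mean-abs")
  # force exact normalized values as printed
  imp$normalized <- c(0.055, 0.089)
  fake_ci <- function(ci, se) structure(
    list(ci = ci, se = se, lower = ci - 1.96 * se,
         upper = ci + 1.96 * se, conf = 0.95, p_value = 1e-5,
         stars = "***", method = "feature", rank_variable = "w",
         n = 10, mu = 1), class = "concindex")
  dec <- product_decomposition(
    imp, list(economic = fake_ci(0.3029, 0.0021),
              autonomy = fake_ci(-0.111, 0.005)), "wealth_quintile")
  d <- dec$rows
  expect_equal(round_half_away(d$contribution[d$feature == "economic"], 3),
               0.017)
  expect_equal(round_half_away(d$contribution[d$feature == "autonomy"], 3),
               -0.010)
  # D_j = I_j * CI_j holds to machine precision
  expect_equal(d$contribution, d$importance * d$feature_ci,
               tolerance = 1e-12)
  # sign(D) = sign(CI) when I > 0
  expect_equal(sign(d$contribution), sign(d$feature_ci))

  # zero importance kills the contribution regardless of the feature CI
  imp0 <- screenineq:::.importance_result(c("a", "b"), c(0, 1),
                                          "shap-mean-abs")
  dec0 <- product_decomposition(
    imp0, list(a = fake_ci(0.9, 0.01), b = fake_ci(0.1, 0.01)), "w")
  expect_equal(dec0$rows$contribution[dec0$rows$feature == "a"], 0)

  expect_error(product_decomposition(
    imp0, list(a = fake_ci(0.1, 0.01)), "w"), "different feature sets")
})

test_that("full published table is reproduced by the product rule", {
  ref <- decomposition_reference()
  expect_equal(nrow(ref), 60)
  recomputed <- round_half_away(ref$importance * ref$feature_ci,
                                ref$printed_digits)
  ok <- ref$consistent
  # all rows whose printed value is internally consistent reproduce it
  # (+ 0 collapses signed zeros)
  expect_equal(recomputed[ok] + 0, ref$printed_value[ok] + 0)
  # the flagged rows differ from print but agree with their own factors:
  # assert the recomputed values, and that print-vs-product discrepancies
  # are confined to those flagged rows
  expect_equal(sum(!ok), 4)
  expect_false(any(abs(recomputed[!ok] - ref$printed_value[!ok]) < 1e-12))
  expect_equal(recomputed[!ok][ref$rank_variable[!ok] ==
                                 "wealth_quintile"], c(0.015, -0.009))
})

test_that("importance columns of the reference table sum to one", {
  ref <- decomposition_reference()
  for (rv in unique(ref$rank_variable))
    expect_equal(sum(ref$importance[ref$rank_variable == rv]), 1,
                 tolerance = 1e-9)
})

test_that("SHAP-rank decomposition is exactly additive", {
  d <- separable_data(n_per_class = 20)
  model <- fit_model("decision-tree", d, seed = 2,
                     hyper = list(minsplit = 2, cp = 0))
  sh <- shap_values(model, d, d)
  set.seed(4)
  vals <- sample(1:5, nrow(d$X), replace = TRUE)
  R <- fractional_rank(vals, rep(1, nrow(d$X)),
                       rank_spec("wealth_quintile"))
  dec <- shap_rank_decomposition(sh, R)
  expect_lt(abs(dec$residual), 1e-6)
  expect_equal(sum(dec$contributions), dec$total_ci, tolerance = 1e-6)
})

test_that("SHAP-rank contributions vanish for ignored features and
           concentrate for single-feature models", {
  set.seed(61)
  n <- 60
  bg <- toy_encoded(matrix(rnorm(2 * n), ncol = 2))
  m <- toy_linear_model(c(1, 0))
  xs <- toy_encoded(matrix(rnorm(2 * n), ncol = 2))
  # shift predictions positive so mu > 0
  m$intercept <- 5
  sh <- shap_values(m, xs, bg)
  vals <- sample(1:4, n, replace = TRUE)
  R <- fractional_rank(vals, rep(1, n), rank_spec("g", 1:4))
  dec <- shap_rank_decomposition(sh, R)
  expect_equal(unname(dec$contributions["x2"]), 0, tolerance = 1e-10)
  expect_equal(unname(dec$contributions["x1"]), dec$total_ci,
               tolerance = 1e-10)
})

test_that("local-accuracy violations block the decomposition", {
  sh <- structure(
    list(phi = cbind(a = c(0.5, 0.5), b = c(0, 0)), base_value = 0,
         predictions = c(10, 10), feature = c("a", "b"),
         n_background = 2, exact = TRUE),
    class = "shap_matrix")
  R <- fractional_rank(c(1, 2), c(1, 1), rank_spec("g", 1:2))
  expect_error(shap_rank_decomposition(sh, R), "local accuracy")
})

test_that("bootstrap uncertainty matches closed forms", {
  d <- data.frame(x = rnorm(1000, 5, 2))
  # degenerate constant statistic
  cst <- bootstrap_uncertainty(function(dd) 42, d, B = 100, seed = 1)
  expect_equal(unname(cst$se), 0)

  # SE of a sample mean approx sigma / sqrt(n)
  bt <- bootstrap_uncertainty(function(dd) mean(dd$x), d, B = 400,
                              seed = 2)
  expect_lt(abs(bt$se - sd(d$x) / sqrt(1000)) / (sd(d$x) / sqrt(1000)),
            0.15)
  expect_error(bootstrap_uncertainty(function(dd) 1, d, B = 50),
               "at least 100")
})

test_that("bootstrap percentile bounds reach nominal coverage", {
  set.seed(9)
  true_mean <- 2
  covered <- 0
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    d <- data.frame(x = rexp(300, 1 / true_mean))
    bt <- bootstrap_uncertainty(function(dd) mean(dd$x), d, B = 150,
                                seed = r, conf = 0.9)
    if (bt$lower <= true_mean && true_mean <= bt$upper)
      covered <- covered + 1
  }
  expect_gte(covered / n_rep, 0.8)
})
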