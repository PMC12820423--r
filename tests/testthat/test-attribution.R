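test_that("SHAP of an additive model is the centred feature value", {
  # f(x) = x1 + x2: under the interventional value function the exact
  # Shapley value is phi_j = x_j - mean(background x_j)
  set.seed(101)
  bg <- toy_encoded(matrix(rnorm(40), ncol = 2))
  xs <- toy_encoded(matrix(rnorm(10), ncol = 2))
  m <- toy_linear_model(c(1, 1))
  sh <- shap_values(m, xs, bg)
  expect_true(sh$exact)
  for (j in 1:2)
    expect_equal(unname(sh$phi[, j]),
                 unname(xs$X[, j] - mean(bg$X[, j])), tolerance = 1e-12)
  expect_equal(sh$base_value, mean(rowSums(bg$X)), tolerance = 1e-12)
})

test_that("a feature the model ignores gets zero attribution", {
  set.seed(7)
  bg <- toy_encoded(matrix(rnorm(60), ncol = 3))
  xs <- toy_encoded(matrix(rnorm(15), ncol = 3))
  m <- toy_linear_model(c(2, 0, -1))
  sh <- shap_values(m, xs, bg)
  expect_equal(unname(sh$phi[, 2]), rep(0, 5), tolerance = 1e-12)

  phi1 <- brute_force_shapley(m, xs$X[1, ], bg)
  expect_equal(unname(phi1["x2"]), 0, tolerance = 1e-12)
})

test_that("local accuracy and efficiency hold for every record", {
  d <- separable_data(n_per_class = 15)
  model <- fit_model("decision-tree", d, seed = 3,
                     hyper = list(minsplit = 2, cp = 0))
  sh <- shap_values(model, d, d)
  resid <- sh$base_value + rowSums(sh$phi) - sh$predictions
  expect_lt(max(abs(resid)), 1e-6)
  # efficiency: mean contributions bridge base value to mean prediction
  expect_lt(abs(sum(colMeans(sh$phi)) -
                  (mean(sh$predictions) - sh$base_value)), 1e-6)
})

test_that("brute-force oracle closed forms: single player and symmetry", {
  set.seed(15)
  bg1 <- toy_encoded(matrix(rnorm(20), ncol = 1))
  m1 <- toy_linear_model(3, feature_names = "x1")
  x <- bg1$X[4, , drop = TRUE]
  phi <- brute_force_shapley(m1, c(x1 = x), bg1)
  f_x <- as.numeric(3 * x)
  expect_equal(as.numeric(phi[1]), f_x - attr(phi, "base_value"),
               tolerance = 1e-12)

  # duplicate symmetric features in a symmetric model get equal phi
  Xb <- matrix(rnorm(30), ncol = 2)
  Xb[, 2] <- Xb[, 1]
  bg2 <- toy_encoded(Xb)
  m2 <- toy_linear_model(c(1, 1))
  phi2 <- brute_force_shapley(m2, c(x1 = 0.7, x2 = 0.7), bg2)
  expect_equal(unname(phi2[1]), unname(phi2[2]), tolerance = 1e-12)
})

test_that("exact SHAP equals the brute-force oracle on a tree model", {
  set.seed(9)
  tab <- generate_survey(dgp_config(120, seed = 44,
                                    intercept = qlogis(0.4),
                                    coef = c(wealth_quintile = 0.6,
                                             hesitancy = -0.8)))
  enc <- subset_features(
    encode_features(tab),
    c("wealth_quintile", "education_level", "hesitancy", "safe_water",
      "distance_problem", "autonomy_index"))
  model <- fit_model("decision-tree", enc, seed = 2)
  bg <- slice_records(enc, 1:25)
  xs <- slice_records(enc, 26:33)
  sh <- shap_values(model, xs, bg)
  expect_true(sh$exact)
  for (i in seq_len(nrow(xs$X))) {
    phi_bf <- brute_force_shapley(model, xs$X[i, ], bg)
    expect_equal(unname(sh$phi[i, ]), as.numeric(phi_bf), tolerance = 1e-6)
    expect_equal(sh$base_value, attr(phi_bf, "base_value"),
                 tolerance = 1e-9)
  }
})

test_that("sampling-mode SHAP keeps exact local accuracy and tracks the oracle", {
  set.seed(10)
  bg <- toy_encoded(matrix(rnorm(80), ncol = 4))
  xs <- toy_encoded(matrix(rnorm(12), ncol = 4))
  m <- toy_linear_model(c(1, -2, 0.5, 0))
  sh <- shap_values(m, xs, bg, exact_limit = 2, n_perm = 40, seed = 6)
  expect_false(sh$exact)
  resid <- sh$base_value + rowSums(sh$phi) - sh$predictions
  expect_lt(max(abs(resid)), 1e-10)
  # for an additive model every ordering gives the same marginal: the
  # sampled estimate is exact too
  for (j in 1:4)
    expect_equal(unname(sh$phi[, j]),
                 unname(xs$X[, j] * m$beta[j] -
                          mean(bg$X[, j]) * m$beta[j]),
                 tolerance = 1e-10)
})

test_that("one-hot blocks are attributed as a single feature", {
  tab <- generate_survey(nfhs_like_preset(300, seed = 17))
  enc <- subset_features(encode_features(tab),
                         c("wealth_quintile", "ethnicity", "hesitancy"))
  model <- fit_model("decision-tree", enc, seed = 4)
  sh <- shap_values(model, slice_records(enc, 1:10),
                    slice_records(enc, 11:50))
  expect_equal(colnames(sh$phi),
               c("wealth_quintile", "ethnicity", "hesitancy"))
})

test_that("permutation importance isolates predictive features", {
  set.seed(12)
  n <- 400
  x1 <- rnorm(n)
  noise <- rnorm(n)
  y <- as.integer(x1 > 0)
  d <- toy_encoded(cbind(x1 = x1, noise = noise), y = y)
  model <- fit_model("decision-tree", d, seed = 1,
                     hyper = list(minsplit = 2, cp = 0))
  imp <- permutation_importance(model, d, n_repeats = 5, seed = 3)
  expect_equal(imp$normalized[imp$feature == "x1"], 1, tolerance = 1e-9)
  expect_lt(abs(imp$raw[imp$feature == "noise"]), 0.02)
  expect_equal(sum(imp$normalized), 1, tolerance = 1e-9)
  expect_error(permutation_importance(model, d, n_repeats = 0),
               "at least 1")
})

test_that("permutation importance agrees with one explicit permutation", {
  d <- separable_data(n_per_class = 12)
  model <- fit_model("decision-tree", d, seed = 5,
                     hyper = list(minsplit = 2, cp = 0))
  seed <- 99
  imp <- permutation_importance(model, d, n_repeats = 1, seed = seed)
  # replay the internal draw: first group, first repeat
  baseline <- auroc(predict(model, d), d$y)
  set.seed(seed)
  perm <- sample.int(nrow(d$X))
  Xp <- d$X
  Xp[, 1] <- Xp[perm, 1]
  drop1 <- baseline - auroc(predict(model, Xp), d$y)
  expect_equal(imp$raw[1], drop1)
})

test_that("mean-absolute-SHAP importance reduces correctly", {
  sh <- structure(
    list(phi = cbind(a = c(0.1, -0.3, 0.2), b = c(0, 0, 0)),
         base_value = 0.5, predictions = c(0.6, 0.2, 0.7),
         feature = c("a", "b"), n_background = 10, exact = TRUE),
    class = "shap_matrix")
  imp <- shap_mean_abs(sh)
  expect_equal(imp$raw, c(0.2, 0))
  expect_equal(imp$normalized, c(1, 0))

  sh$phi <- cbind(a = c(0.1, -0.3, 0.2), b = c(-0.1, 0.3, -0.2))
  imp2 <- shap_mean_abs(sh)
  expect_equal(imp2$normalized, c(0.5, 0.5))
})

test_that("normalised importance is invariant to positive rescaling", {
  sh <- structure(
    list(phi = cbind(a = c(0.4, -0.2), b = c(0.1, 0.1)),
         base_value = 0, predictions = c(0.5, -0.1),
         feature = c("a", "b"), n_background = 5, exact = TRUE),
    class = "shap_matrix")
  n1 <- shap_mean_abs(sh)$normalized
  sh$phi <- 13 * sh$phi
  sh$predictions <- NULL  # not used by the reduction
  n2 <- shap_mean_abs(sh)$normalized
  expect_equal(n1, n2)
})
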