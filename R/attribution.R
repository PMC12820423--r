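# Grouped-column view of an encoded matrix: one player per original
# survey variable, so one-hot blocks are attributed as a single feature.
.feature_groups <- function(data) {
  lapply(data$encoding_map, `[[`, "columns")
}

.importance_result <- function(feature, raw, method, n_repeats = NA_integer_,
                               seed = NA_integer_) {
  clipped <- pmax(raw, 0)
  total <- sum(clipped)
  normalized <- if (total > 0) clipped / total else rep(0, length(raw))
  structure(
    list(feature = feature, raw = raw, normalized = normalized,
         method = method, n_repeats = n_repeats, seed = seed),
    class = "importance_result"
  )
}

#' @export
print.importance_result <- function(x, digits = 4, ...) {
  cat(sprintf("Feature importance (%s)\n", x$method))
  print(data.frame(feature = x$feature,
                   raw = round(x$raw, digits),
                   normalized = round(x$normalized, digits)),
        row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.importance_result <- function(x, ...) {
  data.frame(feature = x$feature, raw = x$raw,
             normalized = x$normalized, method = x$method,
             stringsAsFactors = FALSE)
}

#' Permutation feature importance
#'
#' Importance of a variable is the mean drop in a performance metric when
#' its column block is randomly permuted (jointly for one-hot blocks, so a
#' nominal variable is shuffled as one unit), over `n_repeats` independent
#' permutations. The default metric is AUROC. Raw drops and a normalised
#' version (negative drops clipped to zero, then scaled to sum to 1) are
#' returned.
#'
#' @param model An `"uptake_model"`.
#' @param data Labeled `"encoded_matrix"`.
#' @param metric `"auroc"` or `"accuracy"`.
#' @param n_repeats Number of permutations per variable (default 10).
#' @param seed Integer seed.
#' @param threshold Threshold for the accuracy metric.
#' @return An `"importance_result"` with method `"permutation"`.
#' @export
permutation_importance <- function(model, data, metric = "auroc",
                                   n_repeats = 10L, seed = 1L,
                                   threshold = 0.5) {
  stopifnot(inherits(model, "uptake_model"),
            inherits(data, "encoded_matrix"))
  if (n_repeats < 1L) stop("'n_repeats' must be at least 1", call. = FALSE)
  metric <- match.arg(metric, c("auroc", "accuracy"))
  score_fun <- switch(
    metric,
    auroc = function(s) auroc(s, data$y),
    accuracy = function(s) mean(as.integer(s >= threshold) == data$y)
  )
  baseline <- score_fun(predict(model, data))
  groups <- .feature_groups(data)
  set.seed(seed)
  raw <- vapply(names(groups), function(nm) {
    cols <- groups[[nm]]
    drops <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      Xp <- data$X
      perm <- sample.int(nrow(Xp))
      Xp[, cols] <- Xp[perm, cols, drop = FALSE]
      drops[r] <- baseline - score_fun(predict(model, Xp))
    }
    mean(drops)
  }, numeric(1))
  .importance_result(names(groups), unname(raw), "permutation",
                     n_repeats = as.integer(n_repeats),
                     seed = as.integer(seed))
}

# Shared machinery: interventional value function. Coalition members keep
# the explained record's values; everyone else is drawn from the
# background rows, and predictions are averaged over the background.
.coalition_matrix <- function(x, Xb, cols_in) {
  M <- Xb
  if (length(cols_in))
    M[, cols_in] <- matrix(x[cols_in], nrow(Xb), length(cols_in),
                           byrow = TRUE)
  M
}

#' Interventional Shapley values (SHAP)
#'
#' Per-record, per-variable additive contributions under the
#' marginal-expectation (interventional) value function: a coalition's
#' value is the model's mean prediction when coalition variables take the
#' explained record's values and the rest are drawn from a background
#' sample. One-hot blocks are treated as a single player, giving one
#' contribution per original survey variable.
#'
#' For up to `exact_limit` variables the exact Shapley value is computed
#' by enumerating all coalitions. Beyond that a permutation-sampling
#' estimator is used: marginal contributions are accumulated along
#' `n_perm` random player orderings. Because each ordering's
#' contributions telescope from the base value to the record's own
#' prediction, local accuracy (base value + sum of contributions = model
#' prediction) holds exactly in both modes; sampling only adds noise to
#' the split between features.
#'
#' @param model An `"uptake_model"`.
#' @param data `"encoded_matrix"` of records to explain.
#' @param background `"encoded_matrix"` of background records (nonempty;
#'   conventionally up to a few hundred training rows).
#' @param exact_limit Maximum number of variables for exhaustive
#'   enumeration (default 12).
#' @param n_perm Number of sampled orderings in the large-p regime
#'   (default 30).
#' @param seed Seed for the sampled orderings.
#' @return Object of class `"shap_matrix"`: `phi` (n x p matrix, one
#'   column per variable), `base_value` (mean background prediction),
#'   `predictions`, `feature` names, `exact` flag.
#' @export
shap_values <- function(model, data, background, exact_limit = 12L,
                        n_perm = 30L, seed = 1L) {
  stopifnot(inherits(model, "uptake_model"),
            inherits(data, "encoded_matrix"))
  Xb <- if (inherits(background, "encoded_matrix")) background$X else
    as.matrix(background)
  if (nrow(Xb) < 1L) stop("background must be nonempty", call. = FALSE)
  if (!identical(colnames(Xb), colnames(data$X)))
    stop("background and data features differ", call. = FALSE)
  groups <- .feature_groups(data)
  p <- length(groups)
  X <- data$X
  n <- nrow(X)
  B <- nrow(Xb)
  predfun <- function(M) predict(model, M)
  base_value <- mean(predfun(Xb))

  phi <- matrix(0, n, p, dimnames = list(NULL, names(groups)))
  exact <- p <= exact_limit

  if (exact) {
    n_coal <- bitwShiftL(1L, p)
    members <- lapply(seq_len(n_coal) - 1L, function(S)
      which(bitwAnd(S, bitwShiftL(1L, seq_len(p) - 1L)) != 0L))
    coal_size <- lengths(members)
    # Shapley kernel weight for adding one player to a coalition of size s
    wgt <- factorial(0:(p - 1)) * factorial(p - 1 - (0:(p - 1))) /
      factorial(p)
    block <- do.call(rbind, replicate(n_coal, Xb, simplify = FALSE))
    for (i in seq_len(n)) {
      for (S in seq_len(n_coal)) {
        cols <- unlist(groups[members[[S]]], use.names = FALSE)
        rows <- (S - 1L) * B + seq_len(B)
        block[rows, ] <- .coalition_matrix(X[i, ], Xb, cols)
      }
      v <- rowMeans(matrix(predfun(block), nrow = n_coal, byrow = TRUE))
      for (j in seq_len(p)) {
        bit <- bitwShiftL(1L, j - 1L)
        without <- which(bitwAnd(seq_len(n_coal) - 1L, bit) == 0L)
        with_j <- without + bit / 1L
        phi[i, j] <- sum(wgt[coal_size[without] + 1L] *
                           (v[with_j] - v[without]))
      }
    }
  } else {
    set.seed(seed)
    perms <- replicate(n_perm, sample.int(p), simplify = FALSE)
    for (i in seq_len(n)) {
      big <- matrix(0, n_perm * p * B, ncol(X))
      at <- 0L
      for (m in seq_len(n_perm)) {
        mat <- Xb
        for (t in seq_len(p)) {
          cols <- groups[[perms[[m]][t]]]
          mat[, cols] <- matrix(X[i, cols], B, length(cols), byrow = TRUE)
          big[at + seq_len(B), ] <- mat
          at <- at + B
        }
      }
      colnames(big) <- colnames(X)
      v <- rowMeans(matrix(predfun(big), nrow = n_perm * p, byrow = TRUE))
      for (m in seq_len(n_perm)) {
        v_step <- v[(m - 1L) * p + seq_len(p)]
        inc <- diff(c(base_value, v_step))
        phi[i, perms[[m]]] <- phi[i, perms[[m]]] + inc / n_perm
      }
    }
  }

  predictions <- predfun(X)
  resid <- abs(base_value + rowSums(phi) - predictions)
  if (max(resid) > 1e-6)
    stop(sprintf(
      "local accuracy violated (max residual %.3g); explainer bug",
      max(resid)), call. = FALSE)
  structure(
    list(phi = phi, base_value = base_value, predictions = predictions,
         feature = names(groups), n_background = B, exact = exact),
    class = "shap_matrix"
  )
}

#' @export
print.shap_matrix <- function(x, ...) {
  cat(sprintf(
    "SHAP matrix: %d records x %d variables (%s), base value %.4f\n",
    nrow(x$phi), ncol(x$phi),
    if (x$exact) "exact enumeration" else "permutation sampling",
    x$base_value))
  invisible(x)
}

#' Exhaustive Shapley oracle for one record
#'
#' Textbook Shapley value by direct summation over all coalitions of the
#' other players: for each variable `j`,
#' `phi_j = sum_S |S|! (p - |S| - 1)! / p! * (v(S + j) - v(S))`, with the
#' same interventional value function as [shap_values()]. Exponential in
#' the number of variables; refuse beyond 12.
#'
#' @param model An `"uptake_model"`.
#' @param x Named numeric feature vector (one encoded record).
#' @param background `"encoded_matrix"` or matrix of background rows.
#' @param encoding_map Optional encoding map defining variable groups;
#'   defaults to the background's map (one-hot blocks as single players).
#' @return Named numeric vector of Shapley values, one per variable, with
#'   the base value as attribute `"base_value"`.
#' @export
brute_force_shapley <- function(model, x, background,
                                encoding_map = NULL) {
  Xb <- if (inherits(background, "encoded_matrix")) background$X else
    as.matrix(background)
  if (is.null(encoding_map) && inherits(background, "encoded_matrix"))
    encoding_map <- background$encoding_map
  groups <- if (is.null(encoding_map))
    stats::setNames(as.list(seq_along(x)), colnames(Xb))
  else lapply(encoding_map, `[[`, "columns")
  p <- length(groups)
  if (p > 12L) stop("more than 12 players: enumeration refused",
                    call. = FALSE)
  vfun <- function(players) {
    cols <- unlist(groups[players], use.names = FALSE)
    mean(predict(model, .coalition_matrix(x, Xb, cols)))
  }
  phi <- stats::setNames(numeric(p), names(groups))
  others_cache <- new.env()
  for (j in seq_len(p)) {
    others <- setdiff(seq_len(p), j)
    total <- 0
    for (mask in 0:(2^(p - 1) - 1)) {
      S <- others[bitwAnd(mask, bitwShiftL(1L, seq_len(p - 1L) - 1L)) != 0L]
      key_s <- paste0("s", paste(S, collapse = ","))
      v_s <- if (!is.null(others_cache[[key_s]])) others_cache[[key_s]]
      else (others_cache[[key_s]] <- vfun(S))
      key_sj <- paste0("s", paste(sort(c(S, j)), collapse = ","))
      v_sj <- if (!is.null(others_cache[[key_sj]])) others_cache[[key_sj]]
      else (others_cache[[key_sj]] <- vfun(c(S, j)))
      total <- total +
        factorial(length(S)) * factorial(p - length(S) - 1L) /
        factorial(p) * (v_sj - v_s)
    }
    phi[j] <- total
  }
  attr(phi, "base_value") <- vfun(integer(0))
  phi
}

#' Mean absolute SHAP importance
#'
#' Per-variable mean of the absolute Shapley contributions, plus the
#' normalised version summing to 1 (the importance column of the
#' product-rule decomposition).
#'
#' @param shap A `"shap_matrix"`.
#' @return An `"importance_result"` with method `"shap-mean-abs"`.
#' @export
shap_mean_abs <- function(shap) {
  stopifnot(inherits(shap, "shap_matrix"))
  if (nrow(shap$phi) == 0L) stop("empty SHAP matrix", call. = FALSE)
  raw <- colMeans(abs(shap$phi))
  .importance_result(shap$feature, unname(raw), "shap-mean-abs")
}
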