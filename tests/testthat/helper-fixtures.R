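# Shared fixtures: tiny encoded matrices and a toy linear "model" class
# that plugs into the uptake_model predict generic, so attribution code
# can be checked against closed forms.

# Build an encoded_matrix directly from a numeric matrix (every column an
# ordinal feature).
toy_encoded <- function(X, y = NULL, w = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  map <- list()
  for (j in seq_len(ncol(X)))
    map[[colnames(X)[j]]] <- list(type = "ordinal", columns = j,
                                  base = FALSE)
  structure(
    list(X = X, feature_names = colnames(X),
         y = if (is.null(y)) rep(0L, nrow(X)) else as.integer(y),
         w = if (is.null(w)) rep(1, nrow(X)) else w,
         encoding_map = map),
    class = "encoded_matrix"
  )
}

# Deterministic additive model f(x) = intercept + sum(beta * x); class
# inherits from uptake_model so package generics accept it.
toy_linear_model <- function(beta, intercept = 0, feature_names = NULL) {
  if (is.null(feature_names)) feature_names <- names(beta)
  if (is.null(feature_names)) feature_names <- paste0("x", seq_along(beta))
  map <- list()
  for (j in seq_along(feature_names))
    map[[feature_names[j]]] <- list(type = "ordinal", columns = j,
                                    base = FALSE)
  structure(
    list(kind = "toy-linear", beta = unname(beta), intercept = intercept,
         feature_names = feature_names, encoding_map = map,
         seed = 0L, hyper = list()),
    class = c("toy_model", "uptake_model")
  )
}

predict.toy_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "encoded_matrix")) newdata$X else
    as.matrix(newdata)
  X <- X[, object$feature_names, drop = FALSE]
  as.numeric(object$intercept + X %*% object$beta)
}

# registerS3method so dispatch works when tests run from an installed
# package namespace
registerS3method("predict", "toy_model", predict.toy_model,
                 envir = asNamespace("stats"))

# Small linearly separable two-feature classification set.
separable_data <- function(n_per_class = 20, seed = 42) {
  set.seed(seed)
  X <- rbind(
    cbind(stats::rnorm(n_per_class, -2, 0.3), stats::rnorm(n_per_class, -2, 0.3)),
    cbind(stats::rnorm(n_per_class, 2, 0.3), stats::rnorm(n_per_class, 2, 0.3))
  )
  colnames(X) <- c("x1", "x2")
  toy_encoded(X, y = rep(c(0L, 1L), each = n_per_class))
}

# Mann-Whitney AUROC by explicit all-pairs enumeration (oracle).
auroc_all_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}
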