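#' Health-seeking autonomy index
#'
#' Sum score over binary permission items (for example: needs no permission
#' to seek healthcare for herself; needs no permission from her husband to
#' give birth at a facility). Larger values mean more autonomy.
#'
#' @param permission_items Data frame or matrix of at least two binary
#'   (0/1) items, one row per record, no missing values.
#' @return Integer vector of per-record sum scores.
#' @export
build_autonomy_index <- function(permission_items) {
  .sum_score(permission_items, binary = TRUE)
}

#' Perceived quality of care (PQC) index
#'
#' Sum score over items describing perceived service quality: facility
#' timings, presence of healthcare personnel, waiting time, quality of the
#' service rendered. Items must share a common scale.
#'
#' @param quality_items Data frame or matrix of at least two numeric items
#'   on a common scale, no missing values.
#' @return Numeric vector of per-record sum scores.
#' @export
build_pqc_index <- function(quality_items) {
  .sum_score(quality_items, binary = FALSE)
}

.sum_score <- function(items, binary) {
  items <- as.matrix(items)
  if (ncol(items) < 2L)
    stop("an index needs at least two items", call. = FALSE)
  if (anyNA(items))
    stop("item values must not be missing", call. = FALSE)
  if (binary && !all(items %in% c(0, 1)))
    stop("permission items must be binary 0/1", call. = FALSE)
  if (!binary) {
    rng <- apply(items, 2L, function(x) diff(range(x)))
    # items measured on visibly different spreads signal mixed scales
    if (max(rng) > 0 && min(rng) > 0 && max(rng) / min(rng) > 10)
      stop("items appear to be on mixed scales; rescale before summing",
           call. = FALSE)
  }
  out <- rowSums(items)
  if (binary) out <- as.integer(out)
  out
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient of a multi-item scale:
#' `alpha = k/(k-1) * (1 - sum_i var_i / var_total)` where `var_i` are the
#' per-item variances and `var_total` the variance of the item sum.
#'
#' @param item_matrix Numeric matrix or data frame, `n x k`, `k >= 2`.
#' @return Scalar alpha. 1 for perfectly correlated items; 0 for mutually
#'   uncorrelated items of equal variance; can be negative.
#' @examples
#' x <- cbind(a = c(1, 2, 3, 4), b = c(1.1, 2, 2.9, 4.2))
#' cronbach_alpha(x)
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  k <- ncol(m)
  if (k < 2L) stop("need at least two items", call. = FALSE)
  v_items <- apply(m, 2L, stats::var)
  if (any(v_items == 0))
    stop("every item must have positive variance", call. = FALSE)
  v_total <- stats::var(rowSums(m))
  if (v_total == 0) stop("total score has zero variance", call. = FALSE)
  k / (k - 1) * (1 - sum(v_items) / v_total)
}

# Default encoding scheme over the generated survey table: ordinal
# variables as integer scores, nominal variables one-hot. `base` marks the
# socioeconomic rank factors used by the base model.
default_scheme <- function() {
  list(
    wealth_quintile = list(type = "ordinal", base = TRUE),
    education_level = list(type = "ordinal", base = TRUE),
    ethnicity       = list(type = "onehot",  base = TRUE),
    age_group       = list(type = "ordinal", base = FALSE),
    state           = list(type = "onehot",  base = FALSE),
    residence       = list(type = "ordinal", base = FALSE),
    met_chw         = list(type = "ordinal", base = FALSE),
    chw_type        = list(type = "ordinal", base = FALSE),
    female_provider_unavailable = list(type = "ordinal", base = FALSE),
    autonomy_index  = list(type = "ordinal", base = FALSE),
    hesitancy       = list(type = "ordinal", base = FALSE),
    safe_water      = list(type = "ordinal", base = FALSE),
    sanitation      = list(type = "ordinal", base = FALSE),
    distance_problem = list(type = "ordinal", base = FALSE),
    transport_problem = list(type = "ordinal", base = FALSE),
    insurance       = list(type = "ordinal", base = FALSE),
    money_for_treatment = list(type = "ordinal", base = FALSE),
    occupation      = list(type = "ordinal", base = FALSE),
    services_discussed = list(type = "ordinal", base = FALSE),
    pqc_index       = list(type = "ordinal", base = FALSE)
  )
}

#' Encode a survey table as a numeric feature matrix
#'
#' Ordinal and binary variables enter as integer scores; nominal variables
#' (`ethnicity`, `state`) are expanded to one-hot indicator blocks. The
#' outcome `y` and weights `w` are carried through unchanged. The returned
#' `encoding_map` records, per original variable, its type, its columns in
#' the matrix and (for nominal variables) its level order, so encodings are
#' invertible and one-hot blocks can be treated as a single feature by the
#' attribution and decomposition stages.
#'
#' @param table A `"survey_table"` (or any data frame with `y`, `w` and the
#'   scheme's variables).
#' @param scheme Named list mapping each variable to
#'   `list(type = "ordinal"|"onehot", base = TRUE/FALSE)`; defaults to the
#'   generator's variable set. `base = TRUE` marks the socioeconomic rank
#'   factors that form the base feature set.
#' @return An object of class `"encoded_matrix"`: list with `X` (numeric
#'   matrix), `feature_names` (original variable per matrix column),
#'   `y`, `w`, and `encoding_map`.
#' @export
encode_features <- function(table, scheme = default_scheme()) {
  scheme <- scheme[intersect(names(scheme), names(table))]
  missing_vars <- setdiff(names(scheme), names(table))
  if (length(missing_vars))
    stop("variables absent from table: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  if (!length(scheme)) stop("empty encoding scheme", call. = FALSE)
  cols <- list()
  map <- list()
  at <- 0L
  for (nm in names(scheme)) {
    sc <- scheme[[nm]]
    v <- table[[nm]]
    if (identical(sc$type, "onehot")) {
      f <- if (is.factor(v)) v else factor(v)
      lev <- levels(f)
      if (anyNA(f)) stop("unknown category in '", nm, "'", call. = FALSE)
      block <- matrix(0, nrow(table), length(lev),
                      dimnames = list(NULL, paste(nm, lev, sep = ".")))
      block[cbind(seq_len(nrow(table)), as.integer(f))] <- 1
      cols[[nm]] <- block
      map[[nm]] <- list(type = "onehot", levels = lev,
                        columns = at + seq_along(lev),
                        base = isTRUE(sc$base))
      at <- at + length(lev)
    } else {
      x <- as.numeric(v)
      if (anyNA(x)) stop("non-numeric ordinal '", nm, "'", call. = FALSE)
      cols[[nm]] <- matrix(x, ncol = 1, dimnames = list(NULL, nm))
      map[[nm]] <- list(type = "ordinal", columns = at + 1L,
                        base = isTRUE(sc$base))
      at <- at + 1L
    }
  }
  X <- do.call(cbind, cols)
  stopifnot(all(is.finite(X)))
  structure(
    list(
      X = X,
      feature_names = rep(names(scheme),
                          vapply(map, function(m) length(m$columns), 1L)),
      y = as.integer(table$y),
      w = as.numeric(table$w),
      encoding_map = map
    ),
    class = "encoded_matrix"
  )
}

#' @export
print.encoded_matrix <- function(x, ...) {
  cat(sprintf(
    "Encoded matrix: %d records x %d columns (%d variables), %d positive\n",
    nrow(x$X), ncol(x$X), length(x$encoding_map), sum(x$y)))
  invisible(x)
}

#' Decode an encoded matrix back to variable scores
#'
#' Ordinal columns are returned unchanged; each one-hot block is collapsed
#' to the level with the largest indicator (arg-max), so synthetic records
#' produced by interpolation remain decodable.
#'
#' @param data An `"encoded_matrix"`.
#' @return Data frame of original variables (nominal variables as factors),
#'   plus `y` and `w`.
#' @export
decode_features <- function(data) {
  stopifnot(inherits(data, "encoded_matrix"))
  out <- list()
  for (nm in names(data$encoding_map)) {
    m <- data$encoding_map[[nm]]
    if (m$type == "onehot") {
      block <- data$X[, m$columns, drop = FALSE]
      out[[nm]] <- factor(m$levels[max.col(block, ties.method = "first")],
                          levels = m$levels)
    } else {
      out[[nm]] <- data$X[, m$columns]
    }
  }
  out$y <- data$y
  out$w <- data$w
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Restrict an encoded matrix to a subset of variables
#'
#' Keeps the named variables (all their encoded columns) and renumbers the
#' encoding map; used for example to form the base, rank-factors-only
#' feature set.
#'
#' @param data An `"encoded_matrix"`.
#' @param vars Character vector of variable names from the encoding map.
#' @return An `"encoded_matrix"` over the kept variables.
#' @export
subset_features <- function(data, vars) {
  stopifnot(inherits(data, "encoded_matrix"))
  vars <- intersect(names(data$encoding_map), vars)
  keep <- unlist(lapply(data$encoding_map[vars], `[[`, "columns"))
  map <- list()
  at <- 0L
  for (nm in vars) {
    m <- data$encoding_map[[nm]]
    map[[nm]] <- m
    map[[nm]]$columns <- at + seq_along(m$columns)
    at <- at + length(m$columns)
  }
  structure(
    list(X = data$X[, keep, drop = FALSE],
         feature_names = data$feature_names[keep],
         y = data$y, w = data$w, encoding_map = map),
    class = "encoded_matrix"
  )
}

#' Row-subset an encoded matrix
#'
#' @param data An `"encoded_matrix"`.
#' @param idx Integer or logical record index.
#' @return An `"encoded_matrix"` over the selected records.
#' @export
slice_records <- function(data, idx) {
  structure(
    list(X = data$X[idx, , drop = FALSE],
         feature_names = data$feature_names,
         y = data$y[idx], w = data$w[idx],
         encoding_map = data$encoding_map),
    class = "encoded_matrix"
  )
}

#' Synthetic minority oversampling (SMOTE)
#'
#' Balances a binary outcome by generating synthetic minority records on
#' segments between minority nearest neighbours: each synthetic point is
#' `x + u (x' - x)` with `u ~ U(0, 1)` and `x'` one of the `k_neighbors`
#' nearest minority neighbours of `x` (Euclidean distance on z-scored
#' encoded columns; ties broken by lowest row index). One-hot blocks of the
#' interpolated record are rounded back to the arg-max level so synthetic
#' records remain decodable. Synthetic records receive survey weight 1;
#' original records (both classes) pass through unchanged.
#'
#' @param data An `"encoded_matrix"` containing both classes, with minority
#'   count greater than `k_neighbors`.
#' @param k_neighbors Number of nearest minority neighbours (default 5).
#' @param seed Integer seed.
#' @return An `"encoded_matrix"` with equal class counts; attribute
#'   `"synthetic"` flags the generated rows.
#' @export
smote_oversample <- function(data, k_neighbors = 5L, seed = 1L) {
  stopifnot(inherits(data, "encoded_matrix"))
  y <- data$y
  counts <- table(factor(y, levels = c(0, 1)))
  if (any(counts == 0))
    stop("both classes must be present", call. = FALSE)
  minority <- as.integer(names(which.min(counts)))
  min_idx <- which(y == minority)
  n_min <- length(min_idx)
  n_new <- as.integer(max(counts) - n_min)
  if (n_min <= k_neighbors)
    stop("minority count must exceed 'k_neighbors'", call. = FALSE)
  if (n_new == 0L) return(data)

  Xm <- data$X[min_idx, , drop = FALSE]
  # z-score for the neighbour metric only; interpolation stays on the
  # original scale
  mu <- colMeans(data$X)
  sdev <- apply(data$X, 2L, stats::sd)
  sdev[sdev == 0] <- 1
  Z <- sweep(sweep(Xm, 2L, mu), 2L, sdev, "/")
  D <- as.matrix(stats::dist(Z))
  diag(D) <- Inf
  nn <- t(apply(D, 1L, function(d) order(d)[seq_len(k_neighbors)]))

  set.seed(seed)
  base_pick <- rep_len(seq_len(n_min), n_new)
  nb_pick <- nn[cbind(base_pick,
                      sample.int(k_neighbors, n_new, replace = TRUE))]
  u <- stats::runif(n_new)
  Xnew <- Xm[base_pick, , drop = FALSE] +
    u * (Xm[nb_pick, , drop = FALSE] - Xm[base_pick, , drop = FALSE])

  for (m in data$encoding_map) {
    if (m$type == "onehot" && length(m$columns) > 1L) {
      block <- Xnew[, m$columns, drop = FALSE]
      hard <- matrix(0, nrow(block), ncol(block))
      hard[cbind(seq_len(nrow(block)),
                 max.col(block, ties.method = "first"))] <- 1
      Xnew[, m$columns] <- hard
    }
  }

  out <- structure(
    list(
      X = rbind(data$X, Xnew),
      feature_names = data$feature_names,
      y = c(y, rep(minority, n_new)),
      w = c(data$w, rep(1, n_new)),
      encoding_map = data$encoding_map
    ),
    class = "encoded_matrix"
  )
  attr(out, "synthetic") <- c(rep(FALSE, length(y)), rep(TRUE, n_new))
  out
}

#' Train/test and cross-validation split plan
#'
#' Stratified-by-outcome partitioning: a `ratio` train/test holdout plus a
#' `k`-fold assignment of the training records, both seeded. Every stratum
#' must be large enough to appear in each fold.
#'
#' @param data An `"encoded_matrix"`.
#' @param ratio Training fraction, strictly between 0 and 1 (default 0.8).
#' @param k Number of cross-validation folds (default 10).
#' @param seed Integer seed.
#' @return Object of class `"split_plan"`: `train_idx`, `test_idx`, `folds`
#'   (fold id per training record, parallel to `train_idx`), `ratio`, `k`,
#'   `seed`.
#' @export
make_splits <- function(data, ratio = 0.8, k = 10L, seed = 1L) {
  stopifnot(inherits(data, "encoded_matrix"))
  if (ratio <= 0 || ratio >= 1) stop("'ratio' must be in (0, 1)", call. = FALSE)
  if (k < 2L) stop("'k' must be at least 2", call. = FALSE)
  y <- data$y
  set.seed(seed)
  classes <- sort(unique(y))
  sizes <- vapply(classes, function(cls) sum(y == cls), 1L)
  if (any(sizes < k))
    stop("a class stratum is smaller than k", call. = FALSE)
  # per-stratum rounding, then trim/grow the largest stratum so the total
  # training count is exactly round(ratio * n)
  n_tr_cls <- round(ratio * sizes)
  n_tr_cls[which.max(sizes)] <- n_tr_cls[which.max(sizes)] +
    (round(ratio * length(y)) - sum(n_tr_cls))
  train_idx <- integer(0)
  for (i in seq_along(classes)) {
    idx <- which(y == classes[i])
    train_idx <- c(train_idx, sample(idx, n_tr_cls[i]))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(y), train_idx)
  folds <- integer(length(train_idx))
  for (cls in sort(unique(y))) {
    pos <- which(y[train_idx] == cls)
    folds[sample(pos)] <- rep_len(seq_len(k), length(pos))
  }
  structure(
    list(train_idx = train_idx, test_idx = test_idx, folds = folds,
         ratio = ratio, k = as.integer(k), seed = as.integer(seed)),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("Split plan: %d train / %d test (ratio %.2f), %d folds, seed %d\n",
              length(x$train_idx), length(x$test_idx), x$ratio, x$k, x$seed))
  invisible(x)
}
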