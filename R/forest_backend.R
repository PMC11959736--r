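#' Specify a random forest configuration
#'
#' A `forest_spec` pins down everything the trial runner needs to grow a
#' reproducible forest: the tree count, the task, the seed, and which variable
#' importance to compute. A fixed (spec, data) pair yields bit-identical
#' predictions and importances on repeated calls; the run-to-run variation the
#' package measures comes exclusively from changing the seed.
#'
#' @param num_trees Number of trees (positive integer).
#' @param task `"regression"` or `"classification"`.
#' @param seed Integer seed passed to the learner.
#' @param importance Importance measure: `"permutation"` (default) or
#'   `"impurity"`. Permutation importance is the conventional choice for data
#'   with predictors of heterogeneous scales or category counts.
#' @param mtry Variables tried per split; `NULL` uses the learner default
#'   (`floor(sqrt(p))` for classification, `max(floor(p/3), 1)` for
#'   regression).
#' @param min_node_size Minimum terminal node size; `NULL` uses the learner
#'   default.
#' @param sample_fraction Fraction of observations drawn (with replacement)
#'   for each tree. The default 1 is the classical bootstrap, which keeps
#'   out-of-bag sets non-empty with high probability.
#' @return An object of class `rfstab_spec`.
#' @examples
#' forest_spec(500, task = "regression", seed = 1)
#' @export
forest_spec <- function(num_trees, task = c("regression", "classification"),
                        seed = 1L, importance = c("permutation", "impurity"),
                        mtry = NULL, min_node_size = NULL,
                        sample_fraction = 1) {
  task <- match.arg(task)
  importance <- match.arg(importance)
  if (!is.numeric(num_trees) || length(num_trees) != 1L ||
      is.na(num_trees) || num_trees < 1 || num_trees != floor(num_trees)) {
    stop_input("`num_trees` must be a single positive integer")
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_input("`seed` must be a single integer")
  }
  structure(
    list(num_trees = as.integer(num_trees), task = task,
         seed = as.integer(seed), importance = importance, mtry = mtry,
         min_node_size = min_node_size, sample_fraction = sample_fraction),
    class = "rfstab_spec"
  )
}

as_predictor_frame <- function(X, what = "X") {
  if (is.matrix(X)) X <- as.data.frame(X)
  if (!is.data.frame(X)) stop_input(sprintf("`%s` must be a data frame or matrix", what))
  if (is.null(colnames(X)) || anyDuplicated(colnames(X))) {
    stop_input(sprintf("`%s` must have unique column names", what))
  }
  X
}

#' Fit a seeded random forest
#'
#' Thin wrapper around [ranger::ranger()] that enforces the package's
#' reproducibility contract: single-threaded growth under the spec's seed,
#' with per-tree in-bag membership retained so out-of-bag predictions can be
#' reconstructed exactly.
#'
#' @param X Predictor table (data frame or matrix), no missing values.
#' @param y Response: numeric for regression, factor/character (at least two
#'   classes) for classification.
#' @param spec A [forest_spec()].
#' @return An object of class `rfstab_forest` holding the trained learner, the
#'   n-by-num_trees in-bag count matrix, the task, and the training column
#'   names.
#' @examples
#' sim <- simulate_dataset(sim_spec(n = 40, p = 20, seed = 1))
#' f <- fit_forest(sim$genotypes, sim$phenotype, forest_spec(50, seed = 1))
#' @export
fit_forest <- function(X, y, spec) {
  stopifnot(inherits(spec, "rfstab_spec"))
  X <- as_predictor_frame(X)
  if (anyNA(X)) stop_input("`X` contains missing values; impute or filter first")
  n <- nrow(X)
  if (n < 2L) stop_input("need at least 2 observations")
  if (length(y) != n) stop_input("`y` length must equal nrow(X)")
  if (anyNA(y)) stop_input("`y` contains missing values")
  if (spec$task == "classification") {
    y <- if (is.factor(y)) droplevels(y) else factor(y)
    if (nlevels(y) < 2L) stop_input("classification requires at least 2 classes")
  } else {
    if (!is.numeric(y)) stop_input("regression requires a numeric response")
    y <- as.numeric(y)
  }

  fit <- ranger::ranger(
    x = X, y = y,
    num.trees = spec$num_trees,
    mtry = spec$mtry,
    min.node.size = spec$min_node_size,
    replace = TRUE,
    sample.fraction = spec$sample_fraction,
    importance = spec$importance,
    keep.inbag = TRUE,
    seed = spec$seed,
    num.threads = 1L,
    verbose = FALSE
  )
  inbag <- do.call(cbind, fit$inbag.counts)  # n x num_trees counts

  structure(
    list(fit = fit, inbag = inbag, task = spec$task, spec = spec,
         col_names = colnames(X), n = n,
         levels = if (spec$task == "classification") levels(y) else NULL),
    class = "rfstab_forest"
  )
}

check_test_columns <- function(forest, X_test) {
  if (!identical(colnames(X_test), forest$col_names)) {
    stop_schema("test predictor columns must match training columns in name and order")
  }
}

#' Predict from a fitted forest
#'
#' @param forest An `rfstab_forest`.
#' @param X_test Predictor table whose columns match the training columns in
#'   name and order.
#' @return Numeric vector (regression) or factor of class labels
#'   (classification), one entry per row of `X_test`.
#' @export
predict_forest <- function(forest, X_test) {
  stopifnot(inherits(forest, "rfstab_forest"))
  X_test <- as_predictor_frame(X_test, "X_test")
  check_test_columns(forest, X_test)
  if (anyNA(X_test)) stop_input("`X_test` contains missing values")
  p <- predict(forest$fit, data = X_test, num.threads = 1L)$predictions
  if (forest$task == "classification") factor(as.character(p), levels = forest$levels) else as.numeric(p)
}

#' Out-of-bag predictions from a fitted forest
#'
#' For each training individual, aggregates predictions only over the trees
#' whose bootstrap sample excluded that individual: the mean of those trees'
#' predictions for regression, the modal class for classification (ties broken
#' by first class level, deterministically). Individuals that were in-bag for
#' every tree get `NA` and a warning; at practical tree counts (an individual
#' is out of bag for a fraction about exp(-1) of trees) this is rare.
#'
#' @param forest An `rfstab_forest` fitted with in-bag records (always true
#'   for [fit_forest()]).
#' @param X The training predictor table the forest was grown on.
#' @return Vector of length n with possible `NA` entries; factor for
#'   classification.
#' @export
oob_predict <- function(forest, X) {
  stopifnot(inherits(forest, "rfstab_forest"))
  X <- as_predictor_frame(X)
  check_test_columns(forest, X)
  if (nrow(X) != forest$n) stop_input("`X` must be the training table the forest was grown on")
  per_tree <- predict(forest$fit, data = X, predict.all = TRUE,
                      num.threads = 1L)$predictions  # n x T
  oob <- forest$inbag == 0L
  never_oob <- rowSums(oob) == 0L
  if (any(never_oob)) {
    warning(sprintf("%d individual(s) were in-bag for every tree; their OOB prediction is NA",
                    sum(never_oob)), call. = FALSE)
  }
  n <- forest$n
  if (forest$task == "regression") {
    out <- rep(NA_real_, n)
    for (i in which(!never_oob)) out[i] <- mean(per_tree[i, oob[i, ]])
    out
  } else {
    lev <- forest$levels
    out <- rep(NA_character_, n)
    for (i in which(!never_oob)) {
      votes <- tabulate(per_tree[i, oob[i, ]], nbins = length(lev))
      out[i] <- lev[which.max(votes)]
    }
    factor(out, levels = lev)
  }
}

#' Variable importances from a fitted forest
#'
#' @param forest An `rfstab_forest`.
#' @return Named numeric vector of length p, in training column order, of the
#'   importance measure requested in the forest's spec.
#' @export
importances <- function(forest) {
  stopifnot(inherits(forest, "rfstab_forest"))
  imp <- forest$fit$variable.importance
  imp[forest$col_names]
}

#' @export
print.rfstab_forest <- function(x, ...) {
  cat(sprintf("Random forest (%s): %d trees, n = %d, p = %d, seed = %d\n",
              x$task, x$spec$num_trees, x$n, length(x$col_names), x$spec$seed))
  invisible(x)
}
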