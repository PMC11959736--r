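#' Configure a stability trial
#'
#' A trial grows `rep` independently seeded forests at each tree count in
#' `tree_grid`, assembles the repeated predictions (or importances) into a
#' subjects x rep ratings matrix, and measures how well the repetitions agree.
#' Repetition r at grid point g (0-based) uses seed `base_seed + g * rep + r`,
#' so the whole curve is a pure function of (data, config).
#'
#' @param tree_grid Strictly increasing tree counts, length >= 3 (the
#'   downstream logistic fit needs at least 3 points). Default
#'   `c(250, 500, 750, 1000, 2000)`.
#' @param rep Repetitions ("raters") per grid point, >= 2; default 10.
#' @param base_seed Integer seed anchoring the per-repetition seeds.
#' @param selection A [selection_spec()]; default top 15% "high".
#' @param task `"regression"` or `"classification"`.
#' @param importance Importance measure for the importance pathway.
#' @param mtry,min_node_size,sample_fraction Passed through to the learner.
#' @return An object of class `rfstab_config`.
#' @export
trial_config <- function(tree_grid = c(250L, 500L, 750L, 1000L, 2000L),
                         rep = 10L, base_seed = 1L,
                         selection = selection_spec(),
                         task = c("regression", "classification"),
                         importance = c("permutation", "impurity"),
                         mtry = NULL, min_node_size = NULL,
                         sample_fraction = 1) {
  task <- match.arg(task)
  importance <- match.arg(importance)
  tree_grid <- as.integer(tree_grid)
  if (length(tree_grid) < 3L || any(diff(tree_grid) <= 0L) || any(tree_grid < 1L)) {
    stop_input("`tree_grid` must be strictly increasing positive integers, length >= 3")
  }
  if (rep < 2L) stop_input("`rep` must be at least 2")
  structure(
    list(tree_grid = tree_grid, rep = as.integer(rep),
         base_seed = as.integer(base_seed), selection = selection,
         task = task, importance = importance, mtry = mtry,
         min_node_size = min_node_size, sample_fraction = sample_fraction),
    class = "rfstab_config"
  )
}

rep_seed <- function(cfg, g, r) cfg$base_seed + (g - 1L) * cfg$rep + r

spec_at <- function(cfg, num_trees, seed) {
  forest_spec(num_trees, task = cfg$task, seed = seed,
              importance = cfg$importance, mtry = cfg$mtry,
              min_node_size = cfg$min_node_size,
              sample_fraction = cfg$sample_fraction)
}

new_curve <- function(cfg, mode, rows, notes) {
  structure(
    data.frame(num_trees = cfg$tree_grid,
               stability = rows$stability,
               selection_stability = rows$selection_stability,
               runtime_sec = rows$runtime_sec),
    mode = mode, config = cfg, notes = notes,
    class = c("rfstab_curve", "data.frame")
  )
}

# Compute both stabilities for one ratings matrix, turning degenerate
# (zero-information) matrices into flagged NA rows rather than failures.
measure_point <- function(ratings, cfg, mode, select_fun) {
  stab <- tryCatch(
    if (mode == "prediction" && cfg$task == "classification") {
      fleiss_kappa(drop_incomplete_subjects(ratings))
    } else {
      icc_1_1(drop_incomplete_subjects(ratings))
    },
    rfstab_undefined_stability = function(e) structure(NA_real_, msg = conditionMessage(e))
  )
  sel <- tryCatch({
    sm <- select_fun(drop_incomplete_subjects(ratings))
    selection_stability(sm)
  },
  rfstab_undefined_stability = function(e) structure(NA_real_, msg = conditionMessage(e)),
  rfstab_input_error = function(e) structure(NA_real_, msg = conditionMessage(e)))
  list(stability = as.numeric(stab), selection_stability = as.numeric(sel),
       note = c(attr(stab, "msg"), attr(sel, "msg")))
}

run_trials <- function(cfg, mode, n_subjects, one_rep, select_fun, verbose) {
  G <- length(cfg$tree_grid)
  stability <- selection_stability <- runtime <- numeric(G)
  notes <- vector("list", G)
  for (g in seq_len(G)) {
    t_g <- cfg$tree_grid[g]
    ratings <- matrix(NA, nrow = n_subjects, ncol = cfg$rep)
    if (cfg$task == "classification" && mode == "prediction") {
      ratings <- matrix(NA_character_, nrow = n_subjects, ncol = cfg$rep)
    }
    elapsed <- numeric(cfg$rep)
    for (r in seq_len(cfg$rep)) {
      t0 <- proc.time()[["elapsed"]]
      ratings[, r] <- one_rep(t_g, rep_seed(cfg, g, r))
      elapsed[r] <- proc.time()[["elapsed"]] - t0
    }
    m <- measure_point(ratings, cfg, mode, select_fun)
    stability[g] <- m$stability
    selection_stability[g] <- m$selection_stability
    runtime[g] <- mean(elapsed)  # mean fit+predict time of a single forest
    notes[[g]] <- m$note
    if (verbose) {
      message(sprintf("  trees = %6d  stability = %s  selection = %s  (%.2fs/forest)",
                      t_g, format(round(stability[g], 4)),
                      format(round(selection_stability[g], 4)), runtime[g]))
    }
  }
  usable <- sum(!is.na(stability))
  if (usable < 3L) {
    stop_undefined_stability(sprintf(
      "only %d of %d grid points yielded a defined stability; need at least 3 to model the curve",
      usable, G))
  }
  list(stability = stability, selection_stability = selection_stability,
       runtime_sec = runtime, notes = notes)
}

#' Measure prediction stability across a tree-count grid
#'
#' For each tree count, grows `cfg$rep` forests under distinct seeds, predicts
#' the test set (or, with `X_test = NULL`, uses out-of-bag predictions on the
#' training set), and records the agreement among the repeated predictions:
#' ICC(1,1) for regression, Fleiss' kappa for classification, plus the
#' Fleiss' kappa of the top-alpha selection decisions and the mean wall time
#' of a single forest fit+predict.
#'
#' @param X,y Training predictors and response.
#' @param X_test Optional test predictors (same columns as `X`). When absent,
#'   out-of-bag mode is used and individuals never out of bag are dropped
#'   from the ratings matrix.
#' @param cfg A [trial_config()].
#' @param verbose Print per-grid-point progress.
#' @return A stability curve: data frame with columns `num_trees`,
#'   `stability`, `selection_stability`, `runtime_sec` (class `rfstab_curve`).
#'   Grid points with undefined stability are `NA` and noted.
#' @export
run_prediction_trials <- function(X, y, X_test = NULL, cfg = trial_config(),
                                  verbose = FALSE) {
  stopifnot(inherits(cfg, "rfstab_config"))
  X <- as_predictor_frame(X)
  oob <- is.null(X_test)
  if (!oob) {
    X_test <- as_predictor_frame(X_test, "X_test")
    if (!identical(colnames(X_test), colnames(X))) {
      stop_schema("`X_test` columns must match `X` in name and order")
    }
  }
  n_subjects <- if (oob) nrow(X) else nrow(X_test)
  sel_spec <- cfg$selection

  one_rep <- function(t, seed) {
    f <- fit_forest(X, y, spec_at(cfg, t, seed))
    pred <- if (oob) suppressWarnings(oob_predict(f, X)) else predict_forest(f, X_test)
    if (cfg$task == "classification") as.character(pred) else as.numeric(pred)
  }
  select_fun <- function(m) {
    if (cfg$task == "regression") m <- matrix(as.numeric(m), nrow = nrow(m))
    select_from_predictions(m, sel_spec)
  }
  rows <- run_trials(cfg, "prediction", n_subjects, one_rep, select_fun, verbose)
  new_curve(cfg, "prediction", rows, rows$notes)
}

#' Measure variable-importance stability across a tree-count grid
#'
#' As [run_prediction_trials()], but the ratings matrix holds the p
#' per-variable importance estimates of each repetition; the primary
#' stability is always ICC(1,1) (importances are continuous regardless of the
#' task) and selection marks the top-alpha variables per repetition.
#'
#' @inheritParams run_prediction_trials
#' @param alpha Fraction of variables selected per repetition (default 0.05).
#' @return An `rfstab_curve` with one row per grid point.
#' @export
run_importance_trials <- function(X, y, cfg = trial_config(selection = selection_spec(alpha = 0.05)),
                                  alpha = cfg$selection$alpha, verbose = FALSE) {
  stopifnot(inherits(cfg, "rfstab_config"))
  X <- as_predictor_frame(X)
  one_rep <- function(t, seed) {
    f <- fit_forest(X, y, spec_at(cfg, t, seed))
    as.numeric(importances(f))
  }
  select_fun <- function(m) select_from_importances(m, alpha = alpha)
  rows <- run_trials(cfg, "importance", ncol(X), one_rep, select_fun, verbose)
  new_curve(cfg, "importance", rows, rows$notes)
}

#' @export
print.rfstab_curve <- function(x, ...) {
  reps <- attr(x, "config")$rep
  cat(sprintf("Stability curve (%s mode), %d grid points%s:\n",
              attr(x, "mode"), nrow(x),
              if (is.null(reps)) "" else sprintf(", %d repetitions each", reps)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a stability curve to CSV
#'
#' @param curve An `rfstab_curve`.
#' @param path Output file.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Read a stability curve written by [write_curve()]
#'
#' @param path CSV file with columns `num_trees`, `stability`,
#'   `selection_stability`, `runtime_sec`.
#' @param mode Curve mode tag to attach.
#' @return An `rfstab_curve`.
#' @export
read_curve <- function(path, mode = "prediction") {
  d <- utils::read.csv(path)
  need <- c("num_trees", "stability", "selection_stability", "runtime_sec")
  if (!all(need %in% names(d))) {
    stop_schema(sprintf("curve file must have columns: %s", paste(need, collapse = ", ")))
  }
  structure(d[need], mode = mode, class = c("rfstab_curve", "data.frame"))
}
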