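#' Optimise the number of trees for stable predictions
#'
#' The prediction workflow: at each tree count in the grid, grows `rep`
#' forests under distinct seeds, predicts the test individuals (or their
#' out-of-bag values when no test set is given), and measures the agreement
#' among the repeated predictions — ICC(1,1) for a metric response, Fleiss'
#' kappa for a categorical one — plus the agreement of the top-`alpha`
#' selection decisions. A two-parameter logistic curve is then fitted to
#' stability versus tree count and the number of trees is recommended where
#' ten additional trees improve the modelled stability by at most
#' `rec_thresh`.
#'
#' @param X Training predictor table (data frame or matrix).
#' @param y Response: numeric (regression) or factor/character
#'   (classification).
#' @param X_test Optional test predictors with the same columns as `X`;
#'   when `NULL`, out-of-bag predictions on the training set are used.
#' @param alpha Fraction of individuals selected per repetition
#'   (default 0.15).
#' @param select_for Selection criterion: `"high"`, `"low"`, `"zero"` for a
#'   metric response; for a categorical response, the class label(s) that
#'   count as selected (required).
#' @param tree_grid Tree counts measured (default 250, 500, 750, 1000, 2000).
#' @param rep Forest repetitions per grid point (default 10).
#' @param seed Base seed; the whole run is a pure function of
#'   (data, arguments, seed).
#' @param rec_thresh Marginal-stability threshold per ten added trees
#'   (default 1e-6).
#' @param basis Recommendation basis: `"prediction"` (default) or
#'   `"selection"`.
#' @param importance,mtry,min_node_size,sample_fraction Passed to the
#'   learner.
#' @param round_to Recommendation granularity (default 1000).
#' @param verbose Print per-grid-point progress.
#' @return An `rfstab_report`: the measured stability curve, the 2PL fit(s),
#'   the recommendation, runtime projection, and a config echo sufficient to
#'   reproduce the run.
#' @examples
#' \donttest{
#' sim <- simulate_dataset(sim_spec(n = 60, p = 80, seed = 3))
#' rep <- opt_prediction(sim$genotypes, sim$phenotype,
#'                       tree_grid = c(50, 100, 200), rep = 3, seed = 1)
#' rep$recommendation
#' }
#' @export
opt_prediction <- function(X, y, X_test = NULL, alpha = 0.15,
                           select_for = "high",
                           tree_grid = c(250L, 500L, 750L, 1000L, 2000L),
                           rep = 10L, seed = 1L, rec_thresh = 1e-6,
                           basis = c("prediction", "selection"),
                           importance = "permutation", mtry = NULL,
                           min_node_size = NULL, sample_fraction = 1,
                           round_to = 1000L, verbose = FALSE) {
  basis <- match.arg(basis)
  task <- if (is.numeric(y)) "regression" else "classification"
  if (task == "classification") {
    y <- if (is.factor(y)) droplevels(y) else factor(y)
    unknown <- setdiff(select_for, levels(y))
    if (is.null(select_for) || length(unknown)) {
      stop_input(sprintf(paste(
        "categorical response: `select_for` must name the class(es) that count",
        "as selected (response classes: %s)%s"),
        paste(levels(y), collapse = ", "),
        if (length(unknown)) sprintf("; not recognised: %s", paste(unknown, collapse = ", ")) else ""))
    }
    sel <- selection_spec(alpha = alpha, criterion = "classes", classes = select_for)
  } else {
    select_for <- match.arg(select_for, c("high", "low", "zero"))
    sel <- selection_spec(alpha = alpha, criterion = select_for)
  }
  cfg <- trial_config(tree_grid = tree_grid, rep = rep, base_seed = seed,
                      selection = sel, task = task, importance = importance,
                      mtry = mtry, min_node_size = min_node_size,
                      sample_fraction = sample_fraction)
  curve <- run_prediction_trials(X, y, X_test = X_test, cfg = cfg,
                                 verbose = verbose)
  build_report(curve, mode = "prediction", basis = basis,
               rec_thresh = rec_thresh, round_to = round_to, seed = seed)
}

#' Optimise the number of trees for stable variable importances
#'
#' The importance workflow: at each tree count, grows `rep` forests and
#' collects the p per-variable importance estimates of each run into a
#' p x rep matrix; stability is the ICC(1,1) of those repeated importance
#' vectors, and selection stability the Fleiss' kappa of the top-`alpha`
#' variable selections. A 2PL fit and tree-count recommendation follow as in
#' [opt_prediction()].
#'
#' @inheritParams opt_prediction
#' @param alpha Fraction of variables selected per repetition (default 0.05).
#' @param basis `"importance"` (default) or `"selection"`.
#' @return An `rfstab_report`.
#' @export
opt_importance <- function(X, y, alpha = 0.05,
                           tree_grid = c(250L, 500L, 750L, 1000L, 2000L),
                           rep = 10L, seed = 1L, rec_thresh = 1e-6,
                           basis = c("importance", "selection"),
                           importance = "permutation", mtry = NULL,
                           min_node_size = NULL, sample_fraction = 1,
                           round_to = 1000L, verbose = FALSE) {
  basis <- match.arg(basis)
  task <- if (is.numeric(y)) "regression" else "classification"
  cfg <- trial_config(tree_grid = tree_grid, rep = rep, base_seed = seed,
                      selection = selection_spec(alpha = alpha, criterion = "high"),
                      task = task, importance = importance, mtry = mtry,
                      min_node_size = min_node_size,
                      sample_fraction = sample_fraction)
  curve <- run_importance_trials(X, y, cfg = cfg, alpha = alpha,
                                 verbose = verbose)
  build_report(curve, mode = "importance", basis = basis,
               rec_thresh = rec_thresh, round_to = round_to, seed = seed)
}

build_report <- function(curve, mode, basis, rec_thresh, round_to, seed) {
  warns <- character(0)
  wh <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
  })
  fit_primary <- wh(fit_2pl(curve, basis = "stability"))
  fit_selection <- tryCatch(wh(fit_2pl(curve, basis = "selection_stability")),
                            rfstab_error = function(e) NULL)
  rec_fit <- if (basis == "selection") {
    if (is.null(fit_selection)) stop_fit("selection-stability curve could not be fitted; cannot recommend on basis \"selection\"")
    fit_selection
  } else fit_primary
  rec <- wh(recommend_num_trees(rec_fit, rec_thresh = rec_thresh,
                                round_to = round_to))
  rec$basis <- basis
  runtime_proj <- tryCatch(estimate_runtime(curve, rec$num_trees),
                           rfstab_error = function(e) NA_real_)
  structure(
    list(curve = curve, fit = fit_primary, fit_selection = fit_selection,
         recommendation = rec, runtime_at_recommendation = runtime_proj,
         mode = mode, basis = basis, rec_thresh = rec_thresh, seed = seed,
         config = attr(curve, "config"),
         version = as.character(utils::packageVersion("rfstab")),
         warnings = warns),
    class = "rfstab_report"
  )
}

#' @export
print.rfstab_report <- function(x, ...) {
  cat(sprintf("rfstab %s run (%s, seed %d)\n", x$mode, x$config$task, x$seed))
  print(x$curve)
  print(x$fit)
  if (!is.null(x$fit_selection)) print(x$fit_selection)
  print(x$recommendation)
  if (is.finite(x$runtime_at_recommendation)) {
    cat(sprintf("  projected time per forest at recommendation: %.1f s\n",
                x$runtime_at_recommendation))
  }
  if (length(x$warnings)) cat("Warnings:", paste(unique(x$warnings), collapse = "; "), "\n")
  invisible(x)
}

#' Plot a stability run
#'
#' Measured stabilities (points) with the fitted logistic curve (line) on a
#' log tree-count axis; the horizontal dashed line marks the modelled
#' stability at the recommended tree count.
#'
#' @param x An `rfstab_report`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rfstab_report <- function(x, ...) {
  cv <- x$curve
  tt <- exp(seq(log(min(cv$num_trees)), log(max(cv$num_trees) * 10), length.out = 200))
  graphics::plot(cv$num_trees, cv$stability, log = "x",
                 xlab = "number of trees", ylab = paste(x$mode, "stability"),
                 xlim = range(tt), ylim = range(c(cv$stability, 1), na.rm = TRUE),
                 pch = 19, col = "red3", ...)
  graphics::lines(tt, predict_stability(x$fit, tt), col = "steelblue", lwd = 2)
  graphics::abline(h = x$recommendation$stability, col = "red3", lty = 2)
  graphics::legend("bottomright", bty = "n",
                   legend = c("measured", "2PL model",
                              sprintf("stability at %s trees",
                                      format(x$recommendation$num_trees, big.mark = ","))),
                   col = c("red3", "steelblue", "red3"),
                   pch = c(19, NA, NA), lty = c(NA, 1, 2))
  invisible(x)
}

#' Serialise a run report to JSON
#'
#' @param report An `rfstab_report`.
#' @param path Output file.
#' @export
write_report <- function(report, path) {
  out <- list(
    mode = report$mode,
    task = report$config$task,
    seed = report$seed,
    version = report$version,
    tree_grid = report$config$tree_grid,
    repetitions = report$config$rep,
    curve = as.data.frame(report$curve),
    theta1 = report$fit$theta1,
    theta2 = report$fit$theta2,
    residuals = report$fit$residuals,
    selection_theta1 = if (!is.null(report$fit_selection)) report$fit_selection$theta1,
    selection_theta2 = if (!is.null(report$fit_selection)) report$fit_selection$theta2,
    recommendation = list(num_trees = report$recommendation$num_trees,
                          stability = report$recommendation$stability,
                          basis = report$basis,
                          rec_thresh = report$rec_thresh,
                          saturated = report$recommendation$saturated),
    runtime_at_recommendation = report$runtime_at_recommendation,
    warnings = report$warnings
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Filter a SNP genotype table
#'
#' Standard genomic-data preprocessing ahead of the stability workflows:
#' rows sharing an ID are averaged (replicated genotypes), SNP columns with
#' `max_missing` or more missing values or with minor allele frequency of
#' `maf_min` or less are removed, and any remaining missing genotypes are
#' mean-imputed per column. Genotypes are expected as 0/1/2 allele counts.
#'
#' @param table Data frame: first column the individual ID unless `id_col`
#'   says otherwise, remaining columns numeric 0/1/2 genotypes (NA allowed).
#' @param maf_min Drop SNPs with minor allele frequency `<= maf_min`
#'   (default 0.01).
#' @param max_missing Drop SNPs with a missing fraction `>= max_missing`
#'   (default 0.10).
#' @param id_col Name or index of the ID column, or `NULL` if the table is
#'   pure genotypes keyed by row name.
#' @param impute Mean-impute remaining missing genotypes (default TRUE).
#' @return Filtered genotype data frame (IDs as row names), with a
#'   `filter_report` attribute counting dropped/averaged items.
#' @export
preprocess_genotypes <- function(table, maf_min = 0.01, max_missing = 0.10,
                                 id_col = 1L, impute = TRUE) {
  table <- as.data.frame(table)
  if (!is.null(id_col)) {
    ids <- as.character(table[[id_col]])
    G <- table[setdiff(seq_along(table), if (is.numeric(id_col)) id_col else match(id_col, names(table)))]
  } else {
    ids <- rownames(table)
    G <- table
  }
  if (!all(vapply(G, is.numeric, logical(1)))) {
    stop_input("genotype columns must be numeric (0/1/2 allele counts)")
  }
  G <- as.matrix(G)

  n_merged <- 0L
  if (anyDuplicated(ids)) {
    n_merged <- sum(duplicated(ids))
    G <- rowsum(G, group = ids, na.rm = TRUE) /
      rowsum((!is.na(G)) * 1, group = ids)
    G[is.nan(G)] <- NA
    ids <- rownames(G)
  }

  miss_frac <- colMeans(is.na(G))
  drop_missing <- miss_frac >= max_missing
  freq <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  maf[is.na(maf)] <- 0
  drop_maf <- maf <= maf_min
  keep <- !(drop_missing | drop_maf)
  if (!any(keep)) stop_input("all SNP columns were removed by the MAF/missingness filters")
  G <- G[, keep, drop = FALSE]

  n_imputed <- 0L
  if (impute && anyNA(G)) {
    n_imputed <- sum(is.na(G))
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  out <- as.data.frame(G)
  rownames(out) <- ids
  attr(out, "filter_report") <- list(
    n_snps_in = length(keep), n_snps_out = sum(keep),
    dropped_missing = sum(drop_missing), dropped_maf = sum(drop_maf & !drop_missing),
    rows_merged = n_merged, genotypes_imputed = n_imputed)
  out
}
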