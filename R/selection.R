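#' Specify a selection rule
#'
#' Selection turns each column of predicted values (or importances) into a
#' binary selected/rejected decision: the top fraction `alpha` by the chosen
#' criterion. The defaults mirror common practice in genomic selection: the
#' top 15% of individuals by predicted response, the top 5% of variables by
#' importance.
#'
#' @param alpha Fraction selected, in (0, 1).
#' @param criterion `"high"` (largest values), `"low"` (smallest), `"zero"`
#'   (closest to zero), or `"classes"` for categorical predictions.
#' @param classes Character vector of class labels counting as "selected";
#'   required when `criterion = "classes"`.
#' @return An object of class `rfstab_selection_spec`.
#' @export
selection_spec <- function(alpha = 0.15,
                           criterion = c("high", "low", "zero", "classes"),
                           classes = NULL) {
  criterion <- match.arg(criterion)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop_input("`alpha` must be a single number in (0, 1)")
  }
  if (criterion == "classes" && (is.null(classes) || !length(classes))) {
    stop_input("criterion \"classes\" requires at least one class label in `classes`")
  }
  structure(list(alpha = alpha, criterion = criterion,
                 classes = as.character(classes)),
            class = "rfstab_selection_spec")
}

# Number selected per column: round(alpha * n) with a floor of 1
# (round-half-even, R's round()); selecting everyone is an error.
selection_count <- function(alpha, n) {
  k <- max(1L, as.integer(round(alpha * n)))
  if (k >= n) stop_input(sprintf("alpha = %g would select all %d subjects", alpha, n))
  k
}

#' Selection matrix from repeated predictions
#'
#' Per repetition (column), ranks subjects by the criterion and marks the top
#' `k = round(alpha * n)` (at least 1) as selected. Ties at the selection
#' boundary are broken by subject index, deterministically: a random
#' tie-break would inject artificial run-to-run disagreement into the very
#' quantity being measured. The `"classes"` criterion instead selects every
#' subject whose predicted class is in the spec's label set (no fixed count).
#'
#' @param pm Prediction matrix, subjects x repetitions. Numeric for the
#'   rank-based criteria, categorical for `"classes"`.
#' @param spec A [selection_spec()].
#' @return Binary matrix of the same shape, class `rfstab_selection_matrix`:
#'   1 = selected, 0 = rejected.
#' @export
select_from_predictions <- function(pm, spec) {
  stopifnot(inherits(spec, "rfstab_selection_spec"))
  if (is.data.frame(pm)) pm <- as.matrix(pm)
  if (!is.matrix(pm) || nrow(pm) < 2L || ncol(pm) < 1L) {
    stop_input("prediction matrix must have >= 2 subjects")
  }
  if (anyNA(pm)) stop_input("prediction matrix has missing cells")

  if (spec$criterion == "classes") {
    labs <- matrix(as.character(pm), nrow = nrow(pm))
    if (!any(spec$classes %in% labs)) {
      stop_input(sprintf("none of the selection classes (%s) appear among the predictions",
                         paste(spec$classes, collapse = ", ")))
    }
    sel <- (labs %in% spec$classes) * 1L
    sm <- matrix(sel, nrow = nrow(pm))
  } else {
    if (!is.numeric(pm)) stop_input("rank-based selection needs numeric predictions")
    k <- selection_count(spec$alpha, nrow(pm))
    keyed <- switch(spec$criterion,
                    high = -pm, low = pm, zero = abs(pm))
    sm <- apply(keyed, 2L, function(col) {
      sel <- integer(length(col))
      sel[order(col)[seq_len(k)]] <- 1L  # order() is stable: ties -> lower index
      sel
    })
  }
  dimnames(sm) <- dimnames(pm)
  structure(sm, class = c("rfstab_selection_matrix", class(sm)))
}

#' Selection matrix from repeated importances
#'
#' Per repetition, the `round(alpha * p)` variables with the highest
#' importance are selected (importances are "higher is more important"
#' regardless of the task).
#'
#' @param im Importance matrix, variables x repetitions.
#' @param alpha Fraction of variables selected (default 0.05).
#' @return Binary matrix, class `rfstab_selection_matrix`.
#' @export
select_from_importances <- function(im, alpha = 0.05) {
  select_from_predictions(im, selection_spec(alpha = alpha, criterion = "high"))
}

#' Agreement among repeated selection decisions
#'
#' Fleiss' kappa on the two-category (selected/rejected) matrix: 1 when every
#' repetition selects the identical set, near 0 when selections agree no more
#' than chance given the selection fraction.
#'
#' @param sm A selection matrix from [select_from_predictions()] or
#'   [select_from_importances()].
#' @return The selection stability (Fleiss' kappa).
#' @export
selection_stability <- function(sm) {
  m <- matrix(ifelse(unclass(sm) == 1L, "selected", "rejected"), nrow = nrow(sm))
  fleiss_kappa(m)
}

#' Fraction of ever-selected subjects selected in every repetition
#'
#' The number of subjects selected in all R repetitions divided by the number
#' selected in at least one. A companion, more interpretable summary of
#' selection agreement: 1 means the selected set never changed, 0 means no
#' subject survived every repetition.
#'
#' @param sm A selection matrix.
#' @return Fraction in [0, 1].
#' @export
always_selected_fraction <- function(sm) {
  sm <- unclass(sm)
  ever <- rowSums(sm) > 0L
  if (!any(ever)) stop_input("no subject was ever selected")
  always <- rowSums(sm) == ncol(sm)
  sum(always) / sum(ever)
}
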