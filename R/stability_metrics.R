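#' Intraclass correlation ICC(1,1)
#'
#' Single-measures intraclass correlation from the one-way random-effects
#' decomposition: subjects are rows, the R repeated model runs are the
#' "raters" in the columns. With mean squares between subjects (MSB) and
#' within subjects (MSW) from the one-way ANOVA,
#' \deqn{ICC(1,1) = (MSB - MSW) / (MSB + (R - 1) MSW).}
#' The value is 1 exactly when all repetitions agree on every subject while
#' subjects differ from one another; it can be negative when the within-run
#' spread exceeds the between-subject spread.
#'
#' Computed from explicit sums of squares rather than a fitted mixed model, so
#' the single-measures one-way definition holds exactly.
#'
#' @param m Numeric matrix, subjects x repetitions, no missing cells, at least
#'   2 of each.
#' @return The ICC(1,1) value (scalar, at most 1).
#' @examples
#' m <- cbind(1:5, 1:5, 1:5)
#' icc_1_1(m) # exact agreement: 1
#' @export
icc_1_1 <- function(m) {
  m <- check_ratings(m, numeric = TRUE)
  n <- nrow(m); R <- ncol(m)
  grand <- mean(m)
  row_means <- rowMeans(m)
  ssb <- R * sum((row_means - grand)^2)
  ssw <- sum((m - row_means)^2)
  if (ssb == 0 && ssw == 0) {
    stop_undefined_stability(
      "all ratings are identical: both between- and within-subject variance are zero, ICC(1,1) is undefined")
  }
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (R - 1))
  (msb - msw) / (msb + (R - 1) * msw)
}

#' Fleiss' kappa
#'
#' Chance-corrected agreement among a fixed number of raters assigning
#' categories to subjects. With \eqn{n_{ij}} the number of the R raters that
#' assigned category j to subject i, the per-subject agreement is
#' \eqn{P_i = (\sum_j n_{ij}^2 - R) / (R (R - 1))}; kappa compares the mean
#' observed agreement to the agreement expected from the marginal category
#' frequencies: \eqn{\kappa = (\bar P - \bar P_e) / (1 - \bar P_e)} with
#' \eqn{\bar P_e = \sum_j p_j^2}.
#'
#' @param m Matrix of categorical labels (character, factor, or anything
#'   coercible to character), subjects x raters, no missing cells.
#' @return Fleiss' kappa (scalar, at most 1).
#' @examples
#' m <- matrix(c("A", "A", "B", "B"), nrow = 2, ncol = 4)
#' fleiss_kappa(m) # columns identical: 1
#' @export
fleiss_kappa <- function(m) {
  m <- check_ratings(m, numeric = FALSE)
  n <- nrow(m); R <- ncol(m)
  cats <- sort(unique(as.vector(m)))
  counts <- vapply(cats, function(cl) rowSums(m == cl), numeric(n))
  counts <- matrix(counts, nrow = n)  # n x n_categories
  p_i <- (rowSums(counts^2) - R) / (R * (R - 1))
  p_j <- colSums(counts) / (n * R)
  p_bar <- mean(p_i)
  p_e <- sum(p_j^2)
  if (p_e >= 1) {
    stop_undefined_stability(
      "every rater assigned the same single category to every subject: expected agreement is 1, kappa is undefined")
  }
  (p_bar - p_e) / (1 - p_e)
}

check_ratings <- function(m, numeric) {
  if (is.data.frame(m)) m <- as.matrix(m)
  if (!is.matrix(m)) stop_input("ratings must be a matrix (subjects x repetitions)")
  if (anyNA(m)) stop_input("ratings matrix has missing cells; drop incomplete subjects first")
  if (nrow(m) < 2L) stop_input("need at least 2 subjects")
  if (ncol(m) < 2L) stop_input("need at least 2 repetitions")
  if (numeric) {
    if (!is.numeric(m)) stop_input("continuous ratings must be numeric")
  } else {
    m <- matrix(as.character(m), nrow = nrow(m))
  }
  m
}

#' Stability of a repeated-prediction matrix
#'
#' Dispatches to the task-appropriate agreement statistic: [icc_1_1()] for
#' regression (continuous predictions), [fleiss_kappa()] for classification.
#' Subjects with a missing prediction in any repetition (possible in
#' out-of-bag mode) are dropped first; the number dropped is reported via a
#' message when nonzero.
#'
#' @param pm Prediction matrix, subjects x repetitions.
#' @param task `"regression"` or `"classification"`.
#' @return The stability value.
#' @export
prediction_stability <- function(pm, task = c("regression", "classification")) {
  task <- match.arg(task)
  pm <- drop_incomplete_subjects(pm)
  if (task == "regression") icc_1_1(pm) else fleiss_kappa(pm)
}

drop_incomplete_subjects <- function(m) {
  if (is.data.frame(m)) m <- as.matrix(m)
  bad <- apply(m, 1L, anyNA)
  if (any(bad)) {
    message(sprintf("dropping %d subject(s) with missing repetitions before computing stability", sum(bad)))
    m <- m[!bad, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop_input("fewer than 2 subjects with complete repetitions")
  m
}
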