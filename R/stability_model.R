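#' Fit the two-parameter logistic stability model
#'
#' Models stability s as a function of the number of trees t with
#' \deqn{\hat s(t) = \frac{1}{1 + (\theta_1 / t)^{\theta_2}},}
#' a two-parameter logistic in log tree count: \eqn{\theta_1} is the tree
#' count at which the modelled stability is exactly 0.5 and \eqn{\theta_2}
#' the slope there. The lower asymptote is 0 and the upper asymptote 1,
#' matching the range of the agreement statistics being modelled.
#'
#' Parameters are estimated by Levenberg-Marquardt nonlinear least squares
#' ([minpack.lm::nlsLM()]). Starting values come from the closed-form
#' linearisation logit(s) = theta2 (log t - log theta1): an ordinary
#' least-squares line through (log t, logit s), which is robust even when
#' all measured stabilities are close to 1.
#'
#' @param curve An `rfstab_curve` from the trial runner, or any data frame
#'   with columns `num_trees` and the column named in `basis`.
#' @param basis Which stability column to model: `"stability"` (the primary
#'   prediction/importance stability) or `"selection_stability"`.
#' @param weights Optional per-point weights for the residuals (default
#'   unweighted).
#' @return An object of class `rfstab_2pl` with elements `theta1`, `theta2`,
#'   `residuals`, `fitted`, `curve` (the points used), and `basis`.
#' @examples
#' pts <- data.frame(num_trees = c(250, 500, 750, 1000, 2000))
#' pts$stability <- 1 / (1 + (300 / pts$num_trees)^1.5)
#' fit <- fit_2pl(pts)
#' c(fit$theta1, fit$theta2) # recovers (300, 1.5)
#' @export
fit_2pl <- function(curve, basis = "stability", weights = NULL) {
  if (!is.data.frame(curve) || !all(c("num_trees", basis) %in% names(curve))) {
    stop_input(sprintf("`curve` must have columns `num_trees` and `%s`", basis))
  }
  t <- as.numeric(curve$num_trees)
  s <- as.numeric(curve[[basis]])
  keep <- !is.na(s)
  if (any(!keep)) warning(sprintf("excluding %d grid point(s) with undefined stability", sum(!keep)), call. = FALSE)
  if (any(s[keep] <= 0)) {
    warning(sprintf("excluding %d point(s) with stability <= 0 from the logistic fit", sum(s[keep] <= 0)), call. = FALSE)
    keep <- keep & s > 0
  }
  t <- t[keep]; s <- s[keep]
  if (is.null(weights)) w <- rep(1, length(t)) else w <- weights[keep]
  if (length(t) < 3L) stop_fit("need at least 3 usable (trees, stability) points")

  # closed-form initialisation via the logit linearisation
  s_clamped <- pmin(pmax(s, 1e-9), 1 - 1e-9)
  lin <- stats::lm(stats::qlogis(s_clamped) ~ log(t))
  b <- unname(stats::coef(lin)[2]); a <- unname(stats::coef(lin)[1])
  start <- if (is.finite(b) && b > 0) {
    list(theta1 = exp(-a / b), theta2 = b)
  } else {
    list(theta1 = stats::median(t), theta2 = 1)
  }
  start$theta1 <- min(max(start$theta1, 1e-6), 1e9)

  two_pl <- function(par, t) 1 / (1 + (par[["theta1"]] / t)^par[["theta2"]])
  resid_fn <- function(par) sqrt(w) * (s - two_pl(par, t))
  out <- tryCatch(
    minpack.lm::nls.lm(
      par = unlist(start), fn = resid_fn,
      lower = c(theta1 = 1e-9, theta2 = 1e-9),
      upper = c(theta1 = 1e12, theta2 = 1e6),
      control = minpack.lm::nls.lm.control(maxiter = 1024, ftol = 1e-15,
                                           ptol = 1e-15)
    ),
    error = function(e) {
      stop_fit(sprintf("Levenberg-Marquardt fit failed (%s); start was theta1 = %.4g, theta2 = %.4g",
                       conditionMessage(e), start$theta1, start$theta2))
    }
  )
  if (out$info %in% c(0L, 9L)) {
    stop_fit(sprintf("Levenberg-Marquardt did not converge (%s); start was theta1 = %.4g, theta2 = %.4g; residuals: %s",
                     out$message, start$theta1, start$theta2,
                     paste(signif(out$fvec, 3), collapse = ", ")))
  }
  est <- out$par
  fitted_s <- two_pl(est, t)
  degenerate <- stats::sd(s) < 1e-12 || est[["theta1"]] <= 1e-6
  if (degenerate) {
    warning("stability curve carries no information on theta1 (all points at the asymptote); fit is degenerate",
            call. = FALSE)
  }
  structure(
    list(theta1 = unname(est[["theta1"]]), theta2 = unname(est[["theta2"]]),
         residuals = s - fitted_s, fitted = fitted_s,
         curve = data.frame(num_trees = t, stability = s),
         basis = basis, degenerate = degenerate, lm_info = out$info),
    class = "rfstab_2pl"
  )
}

#' Evaluate the fitted stability model
#'
#' @param fit An `rfstab_2pl` (or any list with `theta1`, `theta2`).
#' @param t Tree counts (positive).
#' @return Modelled stability in (0, 1), strictly increasing in `t`;
#'   `predict_stability(fit, fit$theta1)` is exactly 0.5.
#' @export
predict_stability <- function(fit, t) {
  if (any(!is.finite(t)) || any(t <= 0)) stop_input("`t` must be positive")
  1 / (1 + (fit$theta1 / t)^fit$theta2)
}

#' Recommend a number of trees
#'
#' Scans the modelled stability over the tree-count interval 10 to 10,000,000
#' in steps of 10 and finds where the marginal gain from ten additional trees
#' falls to `rec_thresh` or below and stays there: the recommendation is the
#' first grid point after the last ten-tree step whose stability gain exceeds
#' `rec_thresh`, rounded up to the next multiple of `round_to`. Because the
#' ten-tree gain of the logistic rises and then falls, "stays there" matters:
#' taking the first sub-threshold step instead would recommend the scan
#' minimum for any steep curve whose gains are still negligible at 10 trees.
#'
#' @param fit An `rfstab_2pl`.
#' @param rec_thresh Stability gain per ten added trees below which more
#'   trees are judged not worthwhile (default `1e-6`).
#' @param round_to Round the recommendation up to this granularity
#'   (default 1000; set to 1 to disable).
#' @return An object of class `rfstab_recommendation`: `num_trees`,
#'   `stability` (modelled stability there), `basis`, `rec_thresh`,
#'   `saturated` (TRUE when the threshold was never met inside the interval).
#' @export
recommend_num_trees <- function(fit, rec_thresh = 1e-6, round_to = 1000L) {
  if (rec_thresh <= 0) stop_input("`rec_thresh` must be positive")
  grid <- seq(10, 1e7, by = 10)
  s <- predict_stability(fit, grid)
  gain <- diff(s)                      # gain of step grid[i] -> grid[i] + 10
  above <- which(gain > rec_thresh)
  saturated <- FALSE
  if (length(above) == 0L) {
    rec <- grid[1]                     # negligible gain everywhere
  } else if (above[length(above)] == length(gain)) {
    rec <- grid[length(grid)]          # still gaining at the interval end
    saturated <- TRUE
    warning("stability gain still exceeds rec_thresh at 10,000,000 trees; recommendation saturated at the interval bound",
            call. = FALSE)
  } else {
    rec <- grid[above[length(above)] + 1L]
  }
  rec <- as.numeric(ceiling(rec / round_to) * round_to)
  structure(
    list(num_trees = rec, stability = predict_stability(fit, rec),
         basis = fit$basis, rec_thresh = rec_thresh, saturated = saturated),
    class = "rfstab_recommendation"
  )
}

#' Tree count needed for a target stability
#'
#' Closed-form inverse of the logistic model:
#' \eqn{t = \theta_1 (1/s^* - 1)^{-1/\theta_2}}, rounded up to an integer, so
#' the modelled stability at the returned count is at least the target.
#'
#' @param fit An `rfstab_2pl`.
#' @param target_stability Desired stability, in (0, 1).
#' @return Integer tree count.
#' @export
estimate_numtrees <- function(fit, target_stability) {
  s <- target_stability
  if (!is.numeric(s) || any(s <= 0) || any(s >= 1)) {
    stop_input("`target_stability` must be in (0, 1)")
  }
  ceiling(fit$theta1 * (1 / s - 1)^(-1 / fit$theta2))
}

#' Extrapolate runtime to a tree count
#'
#' Forest construction time is linear in the number of trees; this fits an
#' ordinary least-squares line runtime ~ a + b * trees to the per-forest
#' timings recorded on the grid (slope constrained non-negative) and
#' evaluates it at `t`.
#'
#' @param curve An `rfstab_curve` with at least 2 distinct grid points.
#' @param t Tree count(s) to extrapolate to.
#' @return Estimated seconds per forest at `t`.
#' @export
estimate_runtime <- function(curve, t) {
  if (!is.data.frame(curve) || !all(c("num_trees", "runtime_sec") %in% names(curve))) {
    stop_input("`curve` must have columns `num_trees` and `runtime_sec`")
  }
  d <- curve[!is.na(curve$runtime_sec), c("num_trees", "runtime_sec")]
  if (nrow(d) < 2L || length(unique(d$num_trees)) < 2L) {
    stop_input("need runtime measurements at >= 2 distinct tree counts")
  }
  co <- stats::coef(stats::lm(runtime_sec ~ num_trees, data = d))
  if (co[[2]] < 0) co <- c(mean(d$runtime_sec), 0)  # non-negative slope
  as.numeric(co[[1]] + co[[2]] * t)
}

#' @export
print.rfstab_2pl <- function(x, ...) {
  cat(sprintf("2PL stability fit (%s): theta1 = %.4g (trees at stability 0.5), theta2 = %.4g\n",
              x$basis, x$theta1, x$theta2))
  cat(sprintf("  residual SS: %.4g over %d points%s\n", sum(x$residuals^2),
              nrow(x$curve), if (isTRUE(x$degenerate)) "  [degenerate]" else ""))
  invisible(x)
}

#' @export
print.rfstab_recommendation <- function(x, ...) {
  cat(sprintf("Recommended number of trees: %s (basis: %s stability)\n",
              format(x$num_trees, big.mark = ","), x$basis))
  cat(sprintf("  modelled stability there: %.4f (threshold %g per 10 trees%s)\n",
              x$stability, x$rec_thresh,
              if (x$saturated) "; saturated at interval bound" else ""))
  invisible(x)
}
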