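make_noiseless_curve <- function(theta1, theta2,
                                 grid = c(250, 500, 750, 1000, 2000)) {
  data.frame(num_trees = grid, stability = 1 / (1 + (theta1 / grid)^theta2))
}

test_that("fit_2pl recovers parameters exactly from noiseless model data", {
  fit <- fit_2pl(make_noiseless_curve(300, 1.5))
  expect_equal(fit$theta1, 300, tolerance = 1e-6)
  expect_equal(fit$theta2, 1.5, tolerance = 1e-6)
  expect_lt(sum(fit$residuals^2), 1e-12)
})

test_that("fit_2pl stays within 5% of truth under small perturbations", {
  set.seed(5)
  for (i in 1:10) {
    cv <- make_noiseless_curve(300, 1.5)
    cv$stability <- cv$stability + runif(nrow(cv), -1e-3, 1e-3)
    fit <- fit_2pl(cv)
    expect_lt(abs(fit$theta1 - 300) / 300, 0.05)
    expect_lt(abs(fit$theta2 - 1.5) / 1.5, 0.05)
  }
})

test_that("non-positive stability points are excluded with a warning", {
  cv <- make_noiseless_curve(300, 1.5, grid = c(100, 250, 500, 1000, 2000))
  cv$stability[1] <- -0.02
  expect_warning(fit <- fit_2pl(cv), "stability <= 0")
  expect_equal(nrow(fit$curve), 4)
  expect_equal(fit$theta1, 300, tolerance = 1e-4)
  cv$stability[1:3] <- -0.02
  expect_error(suppressWarnings(fit_2pl(cv)), class = "rfstab_fit_error")
})

test_that("an uninformative flat curve is flagged degenerate", {
  cv <- data.frame(num_trees = c(250, 500, 750, 1000), stability = 0.999)
  expect_warning(fit_2pl(cv), "degenerate")
})

test_that("predict_stability anchors at theta1 and increases to the asymptote", {
  fit <- list(theta1 = 500, theta2 = 2)
  expect_identical(predict_stability(fit, 500), 0.5)
  expect_gte(predict_stability(fit, 1e9), 1 - 1e-6)
  fit2 <- list(theta1 = 500, theta2 = 1)
  expect_equal(predict_stability(fit2, 1000), 2 / 3)
  tt <- c(10, 100, 1000, 10000)
  expect_true(all(diff(predict_stability(fit, tt)) > 0))
  expect_error(predict_stability(fit, -5), class = "rfstab_input_error")
})

test_that("recommendation matches a brute-force scan over the ten-tree grid", {
  scan_oracle <- function(theta1, theta2, rec_thresh) {
    grid <- seq(10, 1e7, by = 10)
    s <- 1 / (1 + (theta1 / grid)^theta2)
    gain <- s[-1] - s[-length(s)]
    above <- which(gain > rec_thresh)
    raw <- if (length(above) == 0) 10 else grid[max(above) + 1]
    ceiling(raw / 1000) * 1000
  }
  set.seed(6)
  for (i in 1:20) {
    theta1 <- exp(runif(1, log(50), log(2e5)))
    theta2 <- runif(1, 0.5, 3)
    fit <- list(theta1 = theta1, theta2 = theta2, basis = "stability")
    rec <- recommend_num_trees(fit, rec_thresh = 1e-6)
    expect_equal(rec$num_trees, scan_oracle(theta1, theta2, 1e-6))
  }
})

test_that("recommendation is monotone non-increasing in rec_thresh", {
  fit <- list(theta1 = 800, theta2 = 1.2, basis = "stability")
  threshes <- c(1e-8, 1e-7, 1e-6, 1e-5, 1e-4, 1e-2, 1)
  recs <- vapply(threshes, function(th) recommend_num_trees(fit, rec_thresh = th)$num_trees,
                 numeric(1))
  expect_true(all(diff(recs) <= 0))
  # a threshold no gain can exceed recommends the scan minimum, rounded up
  expect_equal(recs[length(recs)], 1000)
})

test_that("a curve still steep at the interval bound saturates with a warning", {
  # stability 0.09 at 1e7 trees, ten-tree gain there ~8e-8: still above 1e-9
  fit <- list(theta1 = 1e8, theta2 = 1, basis = "stability")
  expect_warning(rec <- recommend_num_trees(fit, rec_thresh = 1e-9), "saturated")
  expect_equal(rec$num_trees, 1e7)
  expect_true(rec$saturated)
})

test_that("estimate_numtrees inverts the model up to integer rounding", {
  fit <- list(theta1 = 500, theta2 = 1)
  expect_equal(estimate_numtrees(fit, 0.5), 500)
  expect_equal(estimate_numtrees(fit, 2 / 3), 1000)
  fit2 <- list(theta1 = 300.4, theta2 = 1.7)
  expect_equal(estimate_numtrees(fit2, 0.5), ceiling(300.4))
  for (s in c(0.5, 0.9, 0.99, 0.999)) {
    t_needed <- estimate_numtrees(fit2, s)
    expect_gte(predict_stability(fit2, t_needed), s)
    # one tree fewer would undershoot (rounding is tight)
    expect_lt(predict_stability(fit2, t_needed - 1), s)
  }
  expect_error(estimate_numtrees(fit, 1), class = "rfstab_input_error")
  expect_error(estimate_numtrees(fit, 0), class = "rfstab_input_error")
})

test_that("runtime extrapolation is an exact fit on exactly linear timings", {
  cv <- data.frame(num_trees = c(250, 500, 1000, 2000),
                   runtime_sec = 1 + 0.002 * c(250, 500, 1000, 2000))
  expect_equal(estimate_runtime(cv, 10000), 21)
  # doubling trees at least doubles the estimate net of the intercept
  e1 <- estimate_runtime(cv, 3000); e2 <- estimate_runtime(cv, 6000)
  expect_equal(e2 - 1, 2 * (e1 - 1), tolerance = 1e-9)
  expect_error(estimate_runtime(cv[1, ], 100), class = "rfstab_input_error")
})
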