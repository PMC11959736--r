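tiny_grid <- c(20, 40, 80)

test_that("opt_prediction composes the runner, the 2PL fit, and the recommendation", {
  sim <- small_regression_sim(n = 50, p = 40)
  rep <- opt_prediction(sim$genotypes, sim$phenotype, X_test = sim$genotypes,
                        tree_grid = tiny_grid, rep = 3, seed = 7)
  expect_s3_class(rep, "rfstab_report")
  refit <- fit_2pl(rep$curve, basis = "stability")
  rerec <- recommend_num_trees(refit, rec_thresh = rep$rec_thresh)
  expect_equal(rep$recommendation$num_trees, rerec$num_trees)
  expect_equal(rep$fit$theta1, refit$theta1, tolerance = 1e-10)
  expect_equal(rep$recommendation$basis, "prediction")
})

test_that("identical invocations reproduce the report except runtimes", {
  sim <- small_regression_sim(n = 50, p = 40)
  r1 <- opt_prediction(sim$genotypes, sim$phenotype, X_test = sim$genotypes,
                       tree_grid = tiny_grid, rep = 3, seed = 7)
  r2 <- opt_prediction(sim$genotypes, sim$phenotype, X_test = sim$genotypes,
                       tree_grid = tiny_grid, rep = 3, seed = 7)
  expect_identical(r1$curve$stability, r2$curve$stability)
  expect_identical(r1$curve$selection_stability, r2$curve$selection_stability)
  expect_identical(r1$recommendation$num_trees, r2$recommendation$num_trees)
  expect_identical(r1$fit$theta1, r2$fit$theta1)
})

test_that("a categorical response demands class labels in select_for", {
  sim <- small_classification_sim(n = 50, p = 40)
  y <- factor(ifelse(sim$phenotype == "high", "case", "control"))
  # default select_for = "high" is not a class of this response
  expect_error(opt_prediction(sim$genotypes, y, X_test = sim$genotypes,
                              tree_grid = tiny_grid, rep = 3),
               class = "rfstab_input_error")
  expect_error(opt_prediction(sim$genotypes, y, X_test = sim$genotypes,
                              select_for = "not_a_class",
                              tree_grid = tiny_grid, rep = 3),
               class = "rfstab_input_error")
  rep <- opt_prediction(sim$genotypes, y, X_test = sim$genotypes,
                        select_for = "case", tree_grid = tiny_grid, rep = 3, seed = 1)
  expect_s3_class(rep, "rfstab_report")
  expect_equal(rep$config$task, "classification")
})

test_that("select_for = zero ranks by absolute predicted value", {
  sim <- small_regression_sim(n = 50, p = 40)
  y_centred <- as.numeric(scale(sim$phenotype, scale = FALSE))
  rep <- opt_prediction(sim$genotypes, y_centred, X_test = sim$genotypes,
                        select_for = "zero", tree_grid = tiny_grid, rep = 3, seed = 3)
  expect_s3_class(rep, "rfstab_report")
})

test_that("opt_importance recommends on the importance basis, or selection on request", {
  sim <- small_regression_sim(n = 50, p = 40)
  ri <- opt_importance(sim$genotypes, sim$phenotype, tree_grid = tiny_grid,
                       rep = 3, seed = 5)
  expect_equal(ri$recommendation$basis, "importance")
  rs <- opt_importance(sim$genotypes, sim$phenotype, tree_grid = c(30, 60, 120, 240),
                       rep = 4, seed = 5, basis = "selection")
  expect_equal(rs$recommendation$basis, "selection")
  resel <- recommend_num_trees(fit_2pl(rs$curve, basis = "selection_stability"))
  expect_equal(rs$recommendation$num_trees, resel$num_trees)
})

test_that("relaxing rec_thresh can only lower the recommendation", {
  sim <- small_regression_sim(n = 50, p = 40)
  strict <- opt_prediction(sim$genotypes, sim$phenotype, X_test = sim$genotypes,
                           tree_grid = tiny_grid, rep = 3, seed = 7, rec_thresh = 1e-6)
  lax <- opt_prediction(sim$genotypes, sim$phenotype, X_test = sim$genotypes,
                        tree_grid = tiny_grid, rep = 3, seed = 7, rec_thresh = 1e-3)
  expect_lte(lax$recommendation$num_trees, strict$recommendation$num_trees)
})

test_that("reports serialise to JSON with the reproduction essentials", {
  sim <- small_regression_sim(n = 50, p = 40)
  rep <- opt_prediction(sim$genotypes, sim$phenotype, X_test = sim$genotypes,
                        tree_grid = tiny_grid, rep = 3, seed = 7)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$seed, 7)
  expect_equal(back$tree_grid, tiny_grid)
  expect_equal(back$theta1, rep$fit$theta1, tolerance = 1e-12)
  expect_equal(back$recommendation$num_trees, rep$recommendation$num_trees)
})

test_that("genotype preprocessing applies the MAF and missingness filters", {
  tab <- data.frame(
    id = c("a", "b", "c", "d", "e", "f", "g", "h", "i", "j"),
    snp_all0 = rep(0, 10),                         # MAF 0: dropped
    snp_rare = c(1, rep(0, 9)),                    # MAF 0.05: kept
    snp_miss = c(NA, 1:9 %% 3),                    # 10% missing exactly: dropped
    snp_common = rep(c(0, 1, 2, 1, 0), 2),         # kept
    snp_low = c(rep(0, 9), 2)                      # freq 0.1 -> kept at maf_min 0.01
  )
  out <- preprocess_genotypes(tab, maf_min = 0.01, max_missing = 0.10)
  expect_setequal(colnames(out), c("snp_rare", "snp_common", "snp_low"))
  rep <- attr(out, "filter_report")
  expect_equal(rep$dropped_maf, 1)
  expect_equal(rep$dropped_missing, 1)

  # hand-computed MAF boundary: frequency exactly maf_min is dropped ("or less")
  tab2 <- data.frame(id = letters[1:10], s1 = c(rep(0, 9), 2), s2 = rep(c(0, 2), 5))
  out2 <- preprocess_genotypes(tab2, maf_min = 0.10)
  expect_equal(colnames(out2), "s2")
})

test_that("replicated genotypes are averaged and leftover gaps mean-imputed", {
  tab <- data.frame(id = c("a", "a", "b", "c"),
                    s1 = c(0, 2, 1, 1), s2 = c(2, 2, NA, 0))
  out <- preprocess_genotypes(tab, maf_min = 0.001, max_missing = 0.5)
  expect_equal(nrow(out), 3)
  expect_equal(out["a", "s1"], 1)              # mean of 0 and 2
  expect_equal(out["b", "s2"], 1)              # imputed column mean of (2, 0)
  expect_false(anyNA(out))
  expect_error(preprocess_genotypes(tab, maf_min = 0.99), class = "rfstab_input_error")
})
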