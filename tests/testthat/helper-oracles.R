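# Independent oracle implementations used to cross-check the package's
# statistics. These deliberately take different routes than the package code:
# the ICC oracle goes through a fitted one-way ANOVA (stats::aov), the kappa
# oracle through an explicit per-subject/per-category loop, and the tree
# oracle traverses ranger trees node by node via treeInfo().

oracle_icc_1_1 <- function(m) {
  d <- data.frame(value = as.vector(m),
                  subject = factor(rep(seq_len(nrow(m)), times = ncol(m))))
  ms <- summary(stats::aov(value ~ subject, data = d))[[1]][["Mean Sq"]]
  msb <- ms[1]; msw <- ms[2]
  R <- ncol(m)
  (msb - msw) / (msb + (R - 1) * msw)
}

oracle_fleiss_kappa <- function(m) {
  n <- nrow(m); R <- ncol(m)
  cats <- unique(as.vector(m))
  P_i <- numeric(n)
  n_ij <- matrix(0, n, length(cats))
  for (i in seq_len(n)) {
    for (j in seq_along(cats)) n_ij[i, j] <- sum(m[i, ] == cats[j])
    P_i[i] <- (sum(n_ij[i, ]^2) - R) / (R * (R - 1))
  }
  p_j <- colSums(n_ij) / (n * R)
  (mean(P_i) - sum(p_j^2)) / (1 - sum(p_j^2))
}

# Predict one row through one ranger tree by explicit traversal.
# ranger sends a value left when it is <= the split value.
oracle_tree_predict <- function(forest, tree, row) {
  ti <- ranger::treeInfo(forest$fit, tree)
  node <- 0L
  repeat {
    r <- ti[ti$nodeID == node, ]
    if (r$terminal) return(r$prediction)
    v <- row[[r$splitvarName]]
    node <- if (v <= r$splitval) r$leftChild else r$rightChild
  }
}

small_regression_sim <- function(seed = 11, n = 40, p = 25) {
  simulate_dataset(sim_spec(n = n, p = p, architecture = "few_strong",
                            n_qtl = 3, h2 = 0.6, seed = seed))
}

small_classification_sim <- function(seed = 12, n = 40, p = 25) {
  simulate_dataset(sim_spec(n = n, p = p, architecture = "few_strong",
                            n_qtl = 3, h2 = 0.6, task = "classification",
                            seed = seed))
}
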