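#' Specify a synthetic genotype/phenotype simulation
#'
#' The simulator emulates the small-n-large-p regime of genomic selection
#' data: n individuals genotyped at p biallelic SNPs coded 0/1/2, with an
#' additive polygenic phenotype. The genetic architecture controls how many
#' SNPs carry true effects: `few_strong` (a handful of large-effect QTLs),
#' `many_weak` (many small-effect QTLs), or `null` (no genetic signal).
#' Heritability h2 sets the fraction of phenotypic variance that is genetic.
#'
#' @param n Individuals (>= 20).
#' @param p SNPs; p >= n is permitted and typical.
#' @param maf_range Range minor allele frequencies are drawn from
#'   (default 0.05-0.5).
#' @param architecture `"few_strong"`, `"many_weak"`, or `"null"`.
#' @param n_qtl Number of causal SNPs; default 5 for `few_strong`,
#'   `ceiling(p/2)` for `many_weak`, 0 for `null`.
#' @param h2 Narrow-sense heritability in `[0, 1]`.
#' @param task `"regression"` (metric phenotype) or `"classification"`
#'   (phenotype dichotomised at `class_quantile`).
#' @param class_quantile Quantile at which the phenotype is thresholded into
#'   two classes ("high"/"low") for the classification task; default 0.5.
#' @param seed Integer seed.
#' @return An object of class `rfstab_sim_spec`.
#' @export
sim_spec <- function(n = 120L, p = 600L, maf_range = c(0.05, 0.5),
                     architecture = c("few_strong", "many_weak", "null"),
                     n_qtl = NULL, h2 = 0.5,
                     task = c("regression", "classification"),
                     class_quantile = 0.5, seed = 1L) {
  architecture <- match.arg(architecture)
  task <- match.arg(task)
  if (n < 20L) stop_input("`n` must be at least 20")
  if (h2 < 0 || h2 > 1) stop_input("`h2` must be in [0, 1]")
  if (architecture == "null") {
    if (h2 > 0) stop_input("`null` architecture requires h2 = 0 (no genetic variance)")
    n_qtl <- 0L
  }
  if (is.null(n_qtl)) {
    n_qtl <- switch(architecture, few_strong = 5L, many_weak = ceiling(p / 2), null = 0L)
  }
  if (n_qtl > p) stop_input("`n_qtl` cannot exceed `p`")
  structure(
    list(n = as.integer(n), p = as.integer(p), maf_range = maf_range,
         architecture = architecture, n_qtl = as.integer(n_qtl), h2 = h2,
         task = task, class_quantile = class_quantile, seed = as.integer(seed)),
    class = "rfstab_sim_spec"
  )
}

#' Simulate SNP genotypes
#'
#' Each SNP gets its own allele frequency drawn uniformly from the spec's MAF
#' range; genotypes are independent Binomial(2, f) counts per individual
#' (Hardy-Weinberg, no linkage disequilibrium).
#'
#' @param spec An [sim_spec()].
#' @return Integer matrix n x p of 0/1/2 genotypes, columns `snp1..snpP`,
#'   with the per-SNP allele frequencies as attribute `freq`.
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "rfstab_sim_spec"))
  set.seed(spec$seed)
  f <- stats::runif(spec$p, spec$maf_range[1], spec$maf_range[2])
  G <- vapply(f, function(fj) stats::rbinom(spec$n, 2L, fj), integer(spec$n))
  dimnames(G) <- list(paste0("ind", seq_len(spec$n)), paste0("snp", seq_len(spec$p)))
  attr(G, "freq") <- f
  G
}

#' Simulate a phenotype from genotypes
#'
#' Additive model y = sum_q beta_q g_q + e. Effects have equal magnitude and
#' random sign within an architecture; the magnitude and the noise variance
#' are scaled so that the realised genetic variance fraction equals h2
#' exactly in the simulated sample. For the classification task the metric
#' phenotype is thresholded at the spec's quantile into "high"/"low".
#'
#' @param genotypes Matrix from [simulate_genotypes()].
#' @param spec The same [sim_spec()].
#' @return List with `y` (numeric vector or factor), `qtl` (causal column
#'   indices), and `beta` (length-p true effect vector).
#' @export
simulate_phenotype <- function(genotypes, spec) {
  stopifnot(inherits(spec, "rfstab_sim_spec"))
  set.seed(spec$seed + 1L)
  n <- nrow(genotypes); p <- ncol(genotypes)
  beta <- numeric(p)
  qtl <- integer(0)
  g_value <- numeric(n)
  if (spec$n_qtl > 0L) {
    qtl <- sort(sample.int(p, spec$n_qtl))
    beta[qtl] <- sample(c(-1, 1), spec$n_qtl, replace = TRUE)
    g_value <- as.numeric(genotypes %*% beta)
    vg <- stats::var(g_value)
    if (vg == 0) {
      # monomorphic draw at every QTL: no realisable genetic variance
      beta[] <- 0; qtl <- integer(0)
    }
  }
  if (spec$h2 > 0 && length(qtl) > 0L) {
    vg <- stats::var(g_value)
    # scale noise so realised Vg / (Vg + Ve) = h2 exactly in this sample:
    # orthogonalise the draw against the genetic value, then fix its variance
    ve <- vg * (1 - spec$h2) / spec$h2
    if (ve > 0) {
      e <- stats::rnorm(n)
      e <- stats::residuals(stats::lm(e ~ g_value))
      e <- e * sqrt(ve / stats::var(e))
    } else {
      e <- numeric(n)
    }
    y <- g_value + e
  } else {
    beta[] <- 0
    y <- stats::rnorm(n)
  }
  if (spec$task == "classification") {
    thr <- stats::quantile(y, spec$class_quantile)
    y <- factor(ifelse(y > thr, "high", "low"), levels = c("high", "low"))
  }
  list(y = y, qtl = qtl, beta = beta)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: genotypes plus phenotype plus truth record.
#'
#' @param spec An [sim_spec()].
#' @return List with `genotypes` (data frame n x p), `phenotype`, `qtl`,
#'   `beta`, and the `spec`.
#' @examples
#' sim <- simulate_dataset(sim_spec(n = 40, p = 60, seed = 7))
#' dim(sim$genotypes)
#' @export
simulate_dataset <- function(spec) {
  G <- simulate_genotypes(spec)
  ph <- simulate_phenotype(G, spec)
  list(genotypes = as.data.frame(G), phenotype = ph$y, qtl = ph$qtl,
       beta = ph$beta, spec = spec)
}

#' Write the standard fixture suite
#'
#' Writes three small deterministic datasets used by the documentation and
#' test suite: a `few_strong` regression fixture, a classification fixture,
#' and a `many_weak` regression fixture. Each dataset is a CSV (first column
#' `id`, then a `y` response column, then the SNP columns) with a JSON truth
#' file recording the causal SNP indices and effects.
#'
#' @param out_dir Writable directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
make_fixture_suite <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  specs <- list(
    regression_few_strong = sim_spec(n = 60, p = 120, architecture = "few_strong",
                                     n_qtl = 3, h2 = 0.6, seed = 101),
    classification = sim_spec(n = 60, p = 120, architecture = "few_strong",
                              n_qtl = 3, h2 = 0.6, task = "classification",
                              seed = 202),
    regression_many_weak = sim_spec(n = 60, p = 120, architecture = "many_weak",
                                    h2 = 0.6, seed = 303)
  )
  paths <- character(0)
  for (nm in names(specs)) {
    sim <- simulate_dataset(specs[[nm]])
    d <- data.frame(id = rownames(sim$genotypes), y = sim$phenotype,
                    sim$genotypes, check.names = FALSE)
    csv <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(d, csv, row.names = FALSE)
    truth <- file.path(out_dir, paste0(nm, "_truth.json"))
    jsonlite::write_json(
      list(qtl = sim$qtl, beta = sim$beta, h2 = specs[[nm]]$h2,
           architecture = specs[[nm]]$architecture, seed = specs[[nm]]$seed),
      truth, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, csv, truth)
  }
  invisible(paths)
}
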