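---
title: "Measuring and modelling random-forest stability as a function of tree count"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling random-forest stability as a function of tree count}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfstab)
```

## The problem

A random forest is an average over randomly grown trees, so any finite
forest is a Monte-Carlo estimate of its own infinite-forest limit. Two runs
on identical data disagree — slightly in predictions, often substantially in
variable importances, and most visibly in *decisions*: which top-15% of
individuals a breeder would select by predicted phenotype, or which top-5%
of SNPs an analyst would carry into follow-up work. The disagreement shrinks
as the number of trees $t$ grows, at a rate that depends strongly on the
data set, and the tree counts software defaults suggest (typically 500) can
be orders of magnitude too small for stable decisions in small-$n$-large-$p$
genomic data.

`rfstab` makes this concrete in three steps: measure stability on a small
grid of tree counts, model the stability–tree-count relationship, and
recommend the tree count beyond which more trees are not worth their cost.

## Stability statistics

Repeating the forest $R$ times (default 10) at a fixed $t$ gives, per test
individual (or per variable), $R$ repeated outputs — a subjects $\times R$
ratings matrix in the language of inter-rater agreement, with the runs as
raters.

* **Continuous outputs** (predictions of a metric response; importance
  vectors): the intraclass correlation in its one-way, single-measures form,
  $$\mathrm{ICC}(1,1) = \frac{MS_B - MS_W}{MS_B + (R-1)\,MS_W},$$
  computed from explicit one-way ANOVA sums of squares (not a fitted mixed
  model), so the single-measures definition holds exactly. It is 1 exactly
  when all runs agree on every subject while subjects differ, and can be
  negative when within-run spread exceeds between-subject spread.
* **Categorical outputs** (predicted classes; binary selected/rejected
  decisions): Fleiss' $\kappa$, the chance-corrected multi-rater agreement.
  Selection stability is Fleiss' $\kappa$ on the matrix obtained by marking,
  per run, the top $k = \mathrm{round}(\alpha n)$ subjects (minimum 1) under
  the chosen criterion — highest, lowest, or closest-to-zero predicted
  value, a named class set for classification, always highest for
  importances.

Two numerical policies are deliberate. First, degenerate zero-information
matrices (all cells identical; or every rater assigning one single category
everywhere, so expected agreement is already 1) raise a typed
`undefined-stability` condition rather than returning `NaN`; the trial
runner converts this into a flagged `NA` row so a curve with at least three
informative points still fits, and aborts otherwise. Second, ties at the
selection boundary are broken by subject index: a random tie-break would
inject artificial disagreement into the very quantity being measured.

`always_selected_fraction()` reports a companion quantity: of the subjects
selected in at least one run, the fraction selected in every run. The
denominator (the union of ever-selected subjects, not $k$) is a definitional
choice and is documented as such.

## The trial runner

For each $t$ in the grid (default 250, 500, 750, 1000, 2000 — small enough
to be cheap, spread enough to pin both logistic parameters) the runner grows
$R$ forests. Repetition $r$ at grid point $g$ (0-based) uses seed
$\mathrm{base} + gR + r$, making the whole curve a pure function of (data,
config); tests assert bit-identical curves across invocations. Forests are
grown by `ranger` with bootstrap resampling (replacement, sample fraction
1.0), single-threaded for determinism, with permutation importance by
default — impurity importance is exposed as an option, and permutation is
the safer default when predictors differ in scale or category count.

Without a test set, stability is measured on out-of-bag predictions: each
individual's prediction aggregates only the trees whose bootstrap sample
excluded it (mean for regression, modal class for classification). An
individual in-bag for every tree — increasingly unlikely as $t$ grows, since
each tree leaves out a fraction $\approx e^{-1}$ of individuals — gets `NA`
and is dropped from the ratings matrix with a logged count.

The per-grid-point runtime recorded is the mean wall time of a *single*
forest fit-plus-predict, which gives a clean linear-in-$t$ signal;
`estimate_runtime()` fits runtime $\sim a + bt$ by ordinary least squares
(slope constrained non-negative) to extrapolate the cost of the
recommendation.

## The two-parameter logistic model

Measured stabilities $(t_j, s_j)$ are fitted with
$$\hat s(t) = \frac{1}{1 + (\theta_1/t)^{\theta_2}},$$
the two-parameter logistic in $\log t$: asymptotes fixed at 0 and 1 (the
range of both agreement statistics), $\theta_1 > 0$ the tree count at
modelled stability 0.5, $\theta_2 > 0$ the slope there. Fitting is
Levenberg–Marquardt (`minpack.lm`), with bound constraints keeping both
parameters positive. Starting values come from the closed-form
linearisation $\mathrm{logit}(s) = \theta_2(\ln t - \ln\theta_1)$: an OLS
line through $(\ln t, \mathrm{logit}\, s)$ (stabilities clamped to
$[10^{-9}, 1-10^{-9}]$ for the logit only), falling back to
$(\mathrm{median}(t), 1)$ if the line slopes the wrong way. Residuals are
unweighted by default (weights are exposed). Points with $s \le 0$ carry no
information under this model and are excluded with a warning; a flat curve
with all points at the upper asymptote is fitted but flagged degenerate,
since such data cannot identify $\theta_1$. On noiseless model-generated
points the fit recovers its generating parameters to relative error below
$10^{-6}$ (a zero-residual global optimum), which the test suite asserts.

## The recommendation rule

The model is scanned over $t = 10, 20, \ldots, 10^7$ and the stability gain
of each ten-tree step computed. The recommended count is the first grid
point after the **last** step whose gain exceeds `rec_thresh` (default
$10^{-6}$), rounded up to the next multiple of 1,000 (the granularity users
expect of such a recommendation; configurable via `round_to`). The "last"
matters: the ten-tree gain of a logistic rises to a mode near $\theta_1$ and
then falls, so for a steep curve with large $\theta_1$ the gains are *also*
negligible at 10 trees, and stopping at the first sub-threshold step would
absurdly recommend the scan minimum while stability is still near zero. If
no step exceeds the threshold the scan minimum is recommended; if the gain
still exceeds it at $10^7$ the recommendation saturates at the interval
bound with a warning. The closed-form inverse
`estimate_numtrees(fit, s*)` $= \lceil \theta_1 (1/s^* - 1)^{-1/\theta_2}
\rceil$ answers the complementary question "how many trees for stability
$s^*$?", and round-trips with `predict_stability()` up to integer rounding.

By default `opt_prediction()` recommends on the prediction-stability fit and
`opt_importance()` on the importance-stability fit; `basis = "selection"`
switches either to a separate 2PL fitted to the selection-stability column,
which typically lies below the primary stability and so yields larger
recommendations.

## The synthetic-data generator

The simulator emulates the features of genomic-selection data that drive the
stability mechanism: $n \ll p$, SNP genotypes 0/1/2 drawn
$\mathrm{Binomial}(2, f_j)$ with per-SNP allele frequencies uniform on a MAF
range (default 0.05–0.5), and an additive phenotype
$y = \sum_q \beta_q g_q + \varepsilon$. Architectures differ in how the
genetic signal is spread: `few_strong` (default 5 QTLs of equal magnitude,
random sign), `many_weak` (default $p/2$), `null` (none). The noise draw is
orthogonalised against the genetic value and rescaled so the realised
$V_g/(V_g+V_e)$ equals $h^2$ exactly in each simulated sample, which makes
heritability a controlled dial rather than an expectation. Truth files
record QTL indices and effects so recovery tests never re-derive them.

What the simulator deliberately omits: linkage disequilibrium (independent
SNPs; the stability mechanism does not depend on it), dominance, epistasis,
population structure, and genotyping error. Passing tests on these fixtures
therefore demonstrate the *mechanism* — stability rises with tree count,
diffuse architectures and smaller samples need more trees — not the absolute
tree counts any real data set requires, which also reflect LD structure and
far larger $p$.

## Problem sizes used by the tests

The end-to-end checks run at desk scale, chosen once as the smallest sizes
at which the mechanism is visible above Monte-Carlo noise: the
reproducibility and monotonicity check uses one simulated data set
($n = 120$, $p = 600$, $h^2 = 0.5$, 5 QTLs) with grid 50–800 and $R = 5$,
averaging 5 replicate curves; the architecture and sample-size comparisons
use $p = 240$, $n \in \{60, 150\}$, grid 25–400, $R = 4$, 5 replicates per
condition, comparing mean recommendations. At these sizes individual curves
wiggle — only averaged, qualitative orderings are asserted.

## Known limitations

* The 2PL assumes stability approaches 1; data whose stability plateaus
  below 1 (severe noise) are still fitted but the recommendation then sits
  where the *model* flattens, not at stability $\approx 1$.
* OOB-mode stability reflects OOB aggregation (about $R/e$ effective trees
  per subject), so its absolute level is below test-set stability at equal
  $t$; the shape in $t$, which is what the fit uses, is comparable.
* `mtry`, node size, and sample fraction are passed through, not tuned; the
  package optimises the tree count only, and assumes those are fixed first.
* Missing genotypes are mean-imputed by `preprocess_genotypes()`; nearest-
  neighbour imputation, standard in genomics pipelines, is left to upstream
  tools.
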