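---
title: "Sparse multi-label regression for subcellular localization: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse multi-label regression for subcellular localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparseloc)
```

## The problem and the model

A protein may reside in several subcellular compartments at once, so
localization prediction is multi-label: the target for protein $i$ is a
non-empty set $\mathcal{Y}_i \subset \{1,\dots,M\}$. The features are GO
term frequencies: protein $i$ is represented by
$\mathbf{q}_i = [f_{i,1},\dots,f_{i,T}]^\top$, where $f_{i,j}$ counts how
often the $j$-th GO term of a $T$-term vocabulary occurs among the
annotations transferred to the protein from its database homologs.
Term-frequency vectors retain more information than 0/1 indicators and
cost nothing extra here, since homolog annotation transfer naturally
produces multiplicities.

The classifier is a bank of $M$ one-vs-rest penalized least-squares
regressions on transformed labels $y_{i,m} = +1$ if $m \in \mathcal{Y}_i$
and $-1$ otherwise. Class $m$ of the elastic-net variant (mEN) minimizes

$$\sum_{i=1}^{N} \left(y_{i,m} - \boldsymbol\beta_m^\top \mathbf{x}_i\right)^2
  + \lambda_m \|\boldsymbol\beta_m\|_1
  + \gamma_m \|\boldsymbol\beta_m\|_2^2,$$

and mLASSO is the $\gamma_m = 0$ special case. Least squares on $\pm 1$
labels is deliberate: it makes the per-class problem a plain penalized
regression whose entire solution path is piecewise linear, and the sign
and magnitude of each weight read directly as evidence for or against a
location. Squared loss on binary labels is of course not a likelihood;
we use the fitted affine score only through its sign and ordering, where
it behaves like any linear discriminant.

Training proceeds in two stages:

1. **Selection.** Fit the $M$ regressions on the full $T$-dimensional
   design. The union of the non-zero supports across classes is the set
   of *essential GO terms* ($S$ of them, $S \le T$).
2. **Refit.** Project the design onto the essential columns and solve
   the same $M$ penalized problems in $S$ dimensions, giving weights
   $\tilde{\boldsymbol\beta}_m$ and intercepts $\varepsilon_{0,m}$.

A query with essential-space features $\mathbf{x}^s$ receives scores
$s_m = \varepsilon_{0,m} + \tilde{\boldsymbol\beta}_m^\top \mathbf{x}^s$
and the predicted set is $\{m : s_m > 0\}$ when non-empty, otherwise the
argmax location (lowest index on exact ties). The threshold sits at zero
because the labels are centered at $\pm 1$; predictions are therefore
never empty, and multi-location proteins arise whenever several
one-vs-rest scores are simultaneously positive.

## The solver

The L1 problems are solved by least angle regression (LARS) with the
lasso modification, tracing the whole coefficient path; a fit at a given
$\lambda$ is linear interpolation between path knots. The elastic net is
reduced *exactly* to a LASSO on augmented data: stack the standardized
design over $\sqrt{\gamma}\,I_T$ and pad the response with $T$ zeros.
With the penalty written as above (the residual sum of squares is not
halved), the subgradient conditions give
$\lambda_{\max} = 2 \max_j |\mathbf{x}_j^\top \mathbf{y}_c|$ on the
standardized problem; our $\lambda$ is twice that of conventions that
halve the RSS, and $2N$ times that of conventions using mean squared
error. `kkt_residual()` certifies any returned fit against these
conditions.

Numerical choices:

* **Standardization.** Columns are centered and scaled to unit sample
  standard deviation and the response is centered, so the penalty is
  scale-free; weights are mapped back to the count scale and the
  intercept recovered from the centering record. The bias is thus fitted
  implicitly rather than penalized. A `standardize = FALSE` escape hatch
  exists for designs that are already on a common scale (the orthonormal
  closed-form checks use it).
* **Ties and degeneracies.** When two variables reach the maximal
  correlation simultaneously, the lower column index enters first.
  Columns whose admission would make the active Gram matrix singular
  (exact duplicates, exhausted rank) are blacklisted and keep weight
  zero; constant columns are zeroed at standardization and can never
  enter. The active Cholesky factor is updated incrementally on joins
  and recomputed on drops (drops are rare).
* **Tolerances.** The KKT certificate uses 1e-8 on the standardized
  scale; path arithmetic uses 1e-12. The independent test oracle is a
  cyclic coordinate-descent solver run to a 1e-12 update norm, and the
  two agree to ~1e-10 per coefficient, comfortably inside the 1e-6 band
  the tests assert.

## Penalty selection

No selection rule ships with the model itself, so the package defaults
to per-class 5-fold cross-validation over a 20-point logarithmic
$\lambda$ grid from $\lambda_{\max}$ down to
$10^{-2}\lambda_{\max}$, minimizing squared prediction error; for mEN the
grid is crossed with $\gamma \in \{0.01, 0.1, 1\}$. Ties prefer the
largest $\lambda$ (then the smallest $\gamma$) — the sparsest model among
the best. One fold assignment is shared by all $M$ classes, which keeps
the one-vs-rest bank equivariant under class reordering. The refit stage
reuses the selection-stage penalties unless overridden: the refit design
is a subset of the selection design, so the penalties remain on a
comparable scale, and re-tuning inside the reduced space would reward
the selection twice. All chosen values are recorded in the model object
and its JSON serialization.

## Homolog transfer and the successive search

Queries are annotated by transfer from database homologs: the ranked
BLAST hits (ascending E-value, ties by descending bit score, then
accession) are scanned and the GO multiset of the *first annotated*
homolog is used, examining at most `max_homologs = 5` candidates. We do
not merge annotations across homologs by default — the successive search
exists to avoid null vectors, not to pool evidence — but
`merge_top_k > 1` exposes the pooling dialect explicitly. During
cross-validation the query's own accession is excluded from its homolog
list (`exclude_self`), otherwise annotation transfer leaks the label.
Five candidates is a pragmatic cap: hits beyond the top few are distant
enough that their annotations are as likely to mislead as to help, and
the hierarchical mapping below is the better remedy for sparse
annotation.

## Hierarchical (HIB) mapping

A query annotated with none of the essential terms projects to the zero
vector, which no affine scorer can use. Because GO terms within a
taxonomy form a DAG, a non-essential term $G$ still carries information
about a nearby essential term $E$. The mapping assigns $E$ an *effective
count* $\sum_G f_G\, w(d(G,E))$, summed over annotated terms within
distance $D$, where $d$ is the shortest-path distance in the undirected
view of the `is_a`/`part_of` edges (cross-taxonomy distances are
infinite) and $w$ a non-increasing decay with $w(0)=1$.

The contribution weights are a configurable family rather than a fixed
formula: the default is $w(d) = 2^{-d}$ with $D = 5$, halving the
evidence per hierarchy step, which keeps direct annotation dominant
($w(0)=1$) while letting a grandparent term contribute a quarter count.
Three dialect switches cover the reasonable alternatives: `decay`
(including user functions), `nearest_only` (attribute each annotated
term only to its closest essential terms instead of all within reach),
and `edge_types` (restrict to `is_a`). Properties the implementation
guarantees and the tests assert: additivity over multisets, monotonicity
in $D$, and exact reduction to the plain projection at $D = 0$.

## Evaluation

Nine metrics are implemented, all in $[0,1]$: overall actual accuracy
(exact set match — the strictest), overall locative accuracy (correct
locative proteins over total locative proteins, where a $k$-location
protein counts $k$ times), per-protein Jaccard accuracy, precision,
recall and F1 (instance-averaged), micro- and macro-averaged F1 over the
$M$ one-vs-rest decisions, and Hamming loss (symmetric difference over
$N \times M$). A class absent from both truth and prediction contributes
F1 = 0 to the macro average by default — the conservative reading, since
scoring an unobserved class as perfect inflates imbalanced benchmarks —
with `include_empty_classes = FALSE` as the alternative.

The LOOCV harness re-runs the *entire* pipeline inside each fold by
default, including vocabulary construction and penalty selection, so the
held-out protein cannot influence any training decision; a `fold_hook`
lets tests assert this mechanically. `global_selection = TRUE` instead
fixes one globally selected essential set and only refits per fold —
faithful to protocols that report cross-validation after a single
feature selection, and measurably optimistic, which is why it is not the
default. A held-out protein with no essential terms and no DAG available
aborts the fold under the strict contract (`on_null = "error"`); the
`"intercept"` fallback scores its zero vector, i.e. predicts from the
class priors encoded in the intercepts.

## Synthetic data: what it emulates, what it does not

`make_planted_dataset()` mimics the statistical shape of GO-frequency
designs: sparse non-negative integer counts (zero-inflated Poisson,
default 70% structural zeros, counts $1+\mathrm{Pois}(1.5)$), correlated
column blocks (size 5, sharing a block pattern with probability 0.7) to
exercise the elastic net's grouping, and a row-sparse planted weight
matrix with exactly $k$ non-zeros per class, magnitudes uniform in
$[0.75, 1.5]$ with random signs — moderate effects relative to unit
counts, so recovery is neither trivial nor hopeless. Labels follow
$\mathrm{sign}(\boldsymbol\beta_m^{*\top}\mathbf{x}_i + b_m +
\sigma\varepsilon)$ with the latent centered per class; noise enters
*before* the sign so the planted linear scorer stays Bayes-optimal, with
`flip_rate` available for plain label noise. Every draw is a
deterministic function of `seed`.

`make_benchmark_like_composition()` reproduces the label-set-size
histogram of the 14-location human benchmark (2580/480/43/3 proteins
with 1/2/3/4 locations; 3106 actual, 3681 locative) at any scale,
sampling location identities by the benchmark's per-location locative
counts. `make_toy_dag()` builds per-taxonomy trees with optional
shortcut edges and a leaf-biased annotation database.

What passing on these generators does **not** show: real GO
co-annotation structure (terms co-occur through the DAG and through
curation practice, not in exchangeable blocks), realistic class
imbalance at full benchmark scale, homolog-transfer noise, or database
versioning effects. Results on synthetic data validate the machinery —
solver exactness, selection behavior, metric arithmetic, contracts —
not field performance.

## Study sizes

The replicated support-recovery study (`support_recovery_study()`) runs
20 replicates at $N = 500$, $T = 200$, $M = 4$, $k = 10$,
$\sigma = 0.5$: large enough that cross-validated mLASSO selection
recovers planted supports reliably, small enough to replicate freely.
The mEN run for the nesting comparison uses the mLASSO's per-class
$\lambda$ with $\gamma = 0.01$: at small $\gamma$ the elastic net is a
strict relaxation of the same problem, which is the regime in which the
"mEN essential set contains the mLASSO essential set" tendency is
expected — it is a tendency of this regime, not a theorem, and it is
tested as a rate over replicates. The acceptance script's end-to-end
demonstration runs full LOOCV with default CV penalties on a 60-protein,
30-term, 3-location planted set.

## Known limitations

* Squared loss on $\pm 1$ labels yields uncalibrated scores; only signs
  and orderings are meaningful. No probability outputs.
* Per-class penalty selection optimizes regression error, not any
  multi-label metric; a metric-driven selection would couple the classes
  and is out of scope.
* The LARS path is exact but serial; designs beyond a few thousand
  columns are better served by warm-started coordinate descent, which is
  kept as the test oracle only.
* The HIB decay family is a modeling choice; nothing in the data
  selects among decays, and conclusions that depend on the decay shape
  should be checked under more than one.
* `read_obo` handles the `[Term]`/`is_a`/`relationship: part_of` subset
  of OBO 1.2/1.4 that GO distributions use, not arbitrary OBO documents.
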