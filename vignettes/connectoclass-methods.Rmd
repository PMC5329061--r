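---
title: "Graph-measure extraction and ensemble classification of structural connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-measure extraction and ensemble classification of structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectoclass)
```

## The problem

Diffusion-weighted MRI tractography summarizes a subject's white-matter
anatomy as a *structural connectome*: a region-by-region matrix whose
entry $W_{ij}$ counts the reconstructed fibers linking cortical regions
$i$ and $j$. With regions taken as 41 Brodmann areas, each subject is an
undirected weighted graph on 41 nodes with at most
$\binom{41}{2} = 820$ edges; an edge exists wherever at least one fiber
connects the pair. Neurodegeneration (Alzheimer's disease, and to a
lesser degree amnestic mild cognitive impairment) perturbs this network
in ways that are often *not* visible as raw connectivity changes at a
single region but as altered routing patterns across it — which is
exactly what nodal graph measures capture.

`connectoclass` implements the full analysis chain:

1. **connectome I/O** — read/validate matrices and cohort manifests,
   build igraph brain graphs;
2. **graph measures** — eleven nodal measures per region, concatenated
   into a 451-entry feature vector per subject;
3. **feature selection** — two-group ANOVA-F ranking with top-$K$
   selection and an accuracy-vs-$K$ sweep;
4. **ensemble classification** — five base learners combined by signed
   weighted voting, with the pairwise Q statistic as a diversity
   diagnostic;
5. **evaluation** — nested stratified 5-fold cross-validation with all
   tuning inside the training folds, repeated-run median confidence
   intervals, and demographic matching statistics;
6. **synthetic data** — a generator of 41-node cohorts with planted,
   localized group effects, so the whole chain is testable without
   imaging data.

## The eleven nodal measures

For a weighted undirected graph $G=(V,E)$, $|V| = n$, with weighted
adjacency $A$ and hop distance $d(v,u)$:

| measure | definition | convention notes |
|---|---|---|
| closeness | $C_v = (n-1)/\sum_u d(v,u)$ | computed over the reachable set, scaled by $r/(n-1)$; isolated node $\to 0$ |
| betweenness | $C_B(v)=\sum_{s \ne t \ne v} \sigma_v(s,t)/\sigma(s,t)$ | unordered pairs, unnormalized |
| eigenvector | leading eigenvector of $A$ | nonnegative, unit Euclidean norm |
| Katz | $\sum_{k\ge1}\sum_u \alpha^k (A^k)_{uv}$ | closed form $(I-\alpha A)^{-1}$; default $\alpha = 0.85/\lambda_{max}$ |
| HITS | authority = hub score on undirected graphs | L1-normalized Perron vector of $A$ |
| degree | $\deg(v)/(n-1)$ | binary edge counts |
| clustering | $2e/(k(k-1))$ | binarized graph; $k<2 \to 0$ |
| efficiency | $\frac{1}{n-1}\sum_{u\ne v} 1/d(v,u)$ | $1/\infty = 0$ |
| PageRank | stationary vector of damped column-stochastic $A$ | damping 0.85, dangling nodes teleport uniformly |
| load | commodity-flow betweenness | ordered pairs, greedy tie-splitting |
| redundancy | fraction of neighbor pairs co-connected via another node | $k<2 \to 0$ |

The feature vector is measure-major — 41 closeness values, then 41
betweenness values, and so on — giving $41 \times 11 = 451$ features
named `<measure>_<node>`.

### Distance convention

Fiber counts are **similarities**, not costs, and nothing forces a
particular weight-to-length map for shortest paths. The default is
binary hop distances (every edge has length 1); all four shortest-path
measures (closeness, betweenness, efficiency, load) honor the same
convention, switchable to `edge_length = "inverse_weight"` (length
$1/W_{ij}$) in `measure_config()`. Spectral measures (eigenvector,
Katz, HITS, PageRank) always act on the weighted adjacency.

### Numerical choices and degenerate inputs

* **Eigenvector centrality** is the projection of the uniform vector
  onto the leading eigenspace of $A$ (dense symmetric
  eigendecomposition). On a connected graph this is the Perron vector;
  when two components tie for the leading eigenvalue the projection is
  still deterministic, and it equals the limit of power iteration from
  a uniform start. Sign is fixed by making the largest-magnitude entry
  positive; nodes outside dominant components score 0.
* **HITS**: on an undirected graph the alternating authority/hub
  update iterates $A^2$, which is *degenerate on bipartite components*
  (on a star the uniform vector is an exact fixed point). The
  iteration therefore runs on $A + sI$ with a small positive shift
  ($s = 0.1\max_v \mathrm{deg}_w(v)$), which leaves the Perron limit
  unchanged and converges on every graph. Convergence is declared when
  the L1 change drops below `hits_tol` (default 1e-12); non-convergence
  within `hits_max_iter` is an error.
* **Katz** requires $0 < \alpha < 1/\lambda_{max}$ and errors with
  "series diverges" otherwise. The default $\alpha$ is recomputed per
  graph as $0.85/\lambda_{max}$ since the attenuation is otherwise
  unidentified across graphs of different spectral radius.
* **PageRank** is solved exactly as the dense linear system
  $x = (1-d)/n + dPx$; isolated nodes get dangling columns $1/n$.
* **Edgeless graphs**: inside `feature_vector()` the spectral measures
  degrade to all-zero vectors (config `on_degenerate = "zero"`), so
  every feature is always finite; calling the measure functions
  directly with `on_degenerate = "error"` raises instead.
* **Ties in load routing** are split equally among successors at equal
  remaining distance (tolerance 1e-10 on length comparisons).

On trees (unique shortest paths), load equals twice the betweenness —
the ordered- vs unordered-pair conventions — which the test suite
asserts, along with brute-force-oracle agreement of all eleven measures
on every non-isomorphic graph with up to six nodes.

## Feature selection

Features are ranked by the two-group one-way ANOVA F statistic
($F = t^2$ of the pooled two-sample t-test), with p-values reported from
$F(1, n-2)$ but *not* thresholded — selection uses rank only, and exact
F ties resolve to the lower feature index so that top-$K$ sets are
nested and deterministic. The accuracy-vs-$K$ sweep (`sweep_k()`)
refits the ranking inside every training fold; the default grid
$\{10, 30, 50, 110, 150, 230, 310, 390, 430, 451\}$ spans from
aggressive selection to none. $K$ is always treated as data-driven
rather than fixed a priori.

## The ensemble

Five base learners — ridge-penalized logistic regression, Gaussian
naive Bayes, SVM (linear/RBF), random forest, and 1-nearest neighbor —
each emit a ±1 vote and a `tanh`-squashed score in $[-1,1]$. The
ensemble decision is

$$C(x) = \mathrm{sign}\Bigl(\sum_{i=1}^{5} w_i\, BC_i(x)\Bigr),$$

with an exactly-zero sum mapped to $-1$, the less severe class (the
clinically more severe class is always coded $+1$: AD in AD-CT and
AD-MCI, MCI in MCI-CT). Weights are refined by exhaustive search over
all 5-tuples from $\{0, 0.5, 1, 2\}$ (minus the all-zero tuple),
scored by voting accuracy on the inner-CV held-out predictions; ties
prefer the tuple closest to uniform, then lexicographic order.
Pairwise diversity is reported through the Q statistic

$$Q = \frac{N^{11}N^{00} - N^{01}N^{10}}{N^{11}N^{00} + N^{01}N^{10}},$$

which is a diagnostic only — it never gates classifier inclusion.
Undefined Q (zero denominator) is reported missing rather than zero.

Implementation notes: Gaussian naive Bayes is implemented in-package
with variance smoothing ($10^{-9}\times$ the largest feature variance)
because zero-variance features are routine after per-fold selection of
nodal measures; features are standardized inside each learner with
training-fold statistics; every stochastic learner derives its seed
from (global seed, outer fold, learner index), making runs exactly
reproducible.

## Nested cross-validation

Outer stratified 5-fold CV estimates generalization; each outer
training set runs an inner stratified 5-fold CV that tunes, in order:
(1) per-learner hyperparameters on the full feature set, (2) the
feature count $K$ (ranking refit per inner fold), (3) the voting
weights on the cached inner-CV base predictions at the chosen $K$. The
stages are sequential rather than a full grid product to keep the
search tractable; the tuned ensemble is then refit on the whole outer
training set and predicts its held-out fold, so each subject is
predicted exactly once and no selection step sees test data.
Stratification is forced by the 15-per-class design (folds of 3+3).

`repeated_run_ci()` reruns the whole procedure with distinct
fold-assignment seeds, tests each metric sample with Shapiro–Wilk
(metrics from small CV runs are rarely normal), and summarizes by the
median with a distribution-free binomial order-statistic 95% interval —
for $n = 100$ repeats that is order statistics 40 and 61.

Demographic matching uses the pooled (equal-variance) two-tailed
t-test; this is the variant that reproduces the reference cohort's
reported age p-values (0.916, 0.957, 0.957) from its raw roster,
which ships as `study_demographics()`.

## The synthetic generator

No public DTI cohort accompanies the reference design, so the
generator *defines* the study conditions used in tests:

* **Topology/weights**: Erdős–Rényi edge presence at density 0.3 over
  the 820 pairs; log-normal fiber counts (meanlog 4, sdlog 1, i.e.
  median ≈ 55 fibers). Real connectomes have geometric and modular
  structure this deliberately omits; the generator exercises the
  pipeline's contracts, not cortical anatomy.
* **Planted effect**: disease groups perturb only edges *incident to*
  a small affected node set (AD: nodes 1, 2, 4, 27, mimicking
  sensorimotor/piriform involvement; MCI: nodes 1, 2) — weights are
  multiplied by $e^{-\delta |Z|}$ and edges deleted with probability
  $\min(0.5, 0.1\delta)$. Perturbing pathways *through* a region
  rather than the region's own values mirrors the interpretation that
  load/redundancy abnormalities reflect parallel-circuit damage.
  Default $\delta = 2$, the smallest value at which the pipeline
  reliably separates AD-like from CT-like classes.
* **Demographics**: age from a truncated normal (74.5 ± 6.7 years,
  range 55–95), education from the reference cohort's empirical year
  levels, sex F with probability 2/3 — drawn identically across groups,
  so groups are matched in expectation as in a case-matched design.

Because groups at $\delta = 0$ are exchangeable, the pipeline must (and
does, in the acceptance tests) stay at chance under label permutation,
hold a uniform feature-p-value distribution at zero effect, rank
affected-node features on top at positive effect, and increase
outer-CV accuracy monotonically in $\delta$.

What passing these tests does **not** show: performance on real DTI
data, robustness to acquisition/tractography variation, or anatomical
validity of selected regions — the generator has no such structure.

## Problem sizes used by the tests

The acceptance checks run the oracle suite over all 208 non-isomorphic
graphs with ≤ 6 nodes, 50 label permutations of one 30-subject cohort,
and 20 seeds at each of five effect sizes (100 nested-CV runs), using
the reduced tuning grids (`nested_cv_config(reduced = TRUE)`: one
hyperparameter candidate per learner, $K \in \{50, 230, 451\}$). These
sizes were chosen so the full suite runs on a single CPU in well under
half an hour while keeping every statistical check adequately powered.

## Known limitations

* The three classification tasks are binary; no three-class model.
* Only nodal measures — no global graph statistics (small-worldness,
  modularity) and no multivariate/embedded feature selection.
* The weighted-vs-binarized ambiguity of shortest-path measures is
  resolved by configuration, not by data.
* Q diversity is reported, not optimized over.
* 1-NN distance ties are broken by `class::knn` under a fixed seed.
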