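---
title: "Phenotype-specific multi-omics networks with moccanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-specific multi-omics networks with moccanet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moccanet)
```

## The model

moccanet reconstructs feature networks that are specific to a phenotype from
one or more omics matrices $X_1, \dots, X_T$ (subjects $\times$ features,
column-standardized) and a phenotype $Y$. The core estimator is sparse
multiple canonical correlation analysis (SmCCA): find per-block weight
vectors $w_1, \dots, w_T$ maximizing

$$\sum_{i<j} a_{i,j}\, w_i^\top X_i^\top X_j w_j \;+\;
  \sum_i b_i\, w_i^\top X_i^\top Y,
\qquad \|w_t\|_2 = 1,\ \ \|w_t\|_1 \le c_t .$$

The $a_{i,j}$ (between-omics) and $b_i$ (omics-phenotype) are nonnegative
*scaling factors* that prioritize parts of the correlation structure; the
LASSO bounds $c_t$ control how many features each block contributes. We
parameterize $c_t = \max(1,\ l_t \sqrt{p_t})$ with a dimensionless fraction
$l_t \in (0,1]$, so the same grid of $l$ values is comparable across blocks
of different widths. Note the floor: when $l_t\sqrt{p_t} \le 1$ the
constraint set admits only a single nonzero coordinate, i.e. the model
degenerates to one feature per block (this matters for narrow blocks; see
"Choices that matter" below).

The problem is solved by block coordinate ascent. Each step replaces $w_t$
by the maximizer of its linearized objective over the constraint set, which
is a soft-thresholded, L2-normalized copy of the partial gradient with the
threshold located by bisection. Every step solves its subproblem exactly, so
the objective is non-decreasing across sweeps (asserted in the tests).
Cross-products $X_i^\top X_j$ are raw (no $1/(n-1)$): the scale cancels in
the argmax, and reported objective values are labelled as raw sums.
Solutions are sign-ambiguous, so each returned $w_t$ is flipped to make its
largest-magnitude coordinate positive — a pure reporting convention.

### Binary phenotypes: the hybrid estimator

Canonical correlation with a 0/1 vector is a poor discriminator, so binary
phenotypes use a five-stage hybrid ([run_hybrid()]):

1. SmCCA *without* the phenotype, at deliberately relaxed penalties
   (default $l = 0.5$), keeps the features that have any between-omics
   connection.
2. Blocks are subset to that support.
3. The subsets are concatenated and sparse PLS discriminant components are
   extracted against the labels ($R = 3$ by default): per component, the
   weight is the same L1/L2 projection applied to $X^\top y$ (centered 0/1
   labels), and the data matrix is deflated by regression on the component
   score (classical PLS1 deflation) before the next extraction.
4. A logistic regression aggregates the $R$ latent factors into one axis;
   its slopes $\alpha$ convert the projection matrix into per-feature
   discriminant weights $W^*_t = Z_t \alpha$. If the likelihood diverges
   (separable factors are common at small $n$) the fit is repeated with a
   tiny L2 penalty ($10^{-4}$) and the fallback is logged.
5. The CCA and discriminant weights are combined per block as
   $W_t = (\gamma_1 \tilde W_t + \gamma_2 W^*_t)/(\gamma_1+\gamma_2)$.

Two details of stage 5 were genuinely open and are the package's own
decisions. Both parts are normalized to unit L2 norm before combining (the
discriminant part must be; doing the same to the CCA part keeps the two
terms commensurable). Both parts are also put under the canonical sign
convention first: the raw sign of $W^*_t$ follows the arbitrary 0/1 label
coding, and without alignment the two parts can exactly cancel on the very
features both consider important — with aligned signs the combination is
invariant to swapping the class labels, which we assert as a property test.

Single-block inputs skip stages 1–2: quantitative phenotypes reduce to
two-set sparse CCA against $Y$, binary ones to the discriminant path alone.

## Choosing the tuning parameters

**Penalties.** K-fold cross-validation ([cv_quantitative()], [cv_binary()]).
For quantitative phenotypes the loss is the *scaled prediction error*
$|\mathrm{trainCC} - \mathrm{testCC}| / |\mathrm{testCC}|$, which penalizes
overfit *and* vanishing test correlation; trainCC/testCC are the
scaling-weighted sums of pairwise score correlations with the weights
normalized to sum to one, averaged over folds before the loss is taken
once. A zero test correlation maps to $+\infty$ so degenerate combinations
are never selected; ties go to the smallest penalties in lexicographic
block order (sparsest model). For binary phenotypes the full hybrid is
refit per fold and scored on held-out subjects; any of accuracy, AUC
(pairwise concordance, ties at half credit), precision, recall or F1 can be
maximized. Binary folds are stratified by class and fail loudly if a
training fold would lose a class. Default grids: $l \in \{0.1,\dots,0.5\}$
per block (quantitative) and $\{0.5,\dots,0.9\}$ per block plus the
classifier penalty (binary) — 125 and 625 combinations for three blocks.

**Scaling factors.** Three routes. (i) Supply them directly
([scaling_scheme()]). (ii) Automated: run two-block sparse CCA per pair at
a stringent penalty (default $l = 0.1$), set
$a_{i,j} = |\hat\rho_{i,j}| / \text{shrinkage}$ and every $b_i = 1$
([pairwise_preliminary_cc()], [auto_scaling_factors()]); the shrinkage
parameter (default 5) down-weights between-omics structure
relative to the phenotype. (iii) Cross-validated: candidate schemes fix the
between-omics factors at 1 and draw the phenotype factors from a simplex
grid (step 0.1) summing to one, then a nested grid search picks the scheme
and penalties jointly ([cv_scaling_search()]). Two normalizations are
conceivable for (iii) — phenotype factors summing to one, or all factors
summing to one; they are mutually inconsistent, and we implement the first
(the between-omics factors then act as a fixed reference unit). For binary runs the automated route instead sets
$\gamma_1$ to the mean absolute pairwise canonical correlation and
$\gamma_2 = 1$ ([auto_gamma()]).

## From weights to networks

**Consensus similarity.** Single sparse fits are unstable in $p \gg n$
regimes, so the network is built from repeated feature subsamples
([run_subsampling()]): each iteration draws
$\lfloor \text{fraction} \cdot p_t \rfloor$ features per block (automated
rule: 0.9 when $p_t < 300$, else 0.7), refits, scatters the weights into a
full-length vector, and accumulates the elementwise absolute outer product
$|w w^\top|$. The average is divided by its maximum entry and the diagonal
zeroed, giving a symmetric similarity in $[0,1]$. The max-rescaling is our
explicit choice (not a fidelity claim): it makes the tree cut height
meaningful across runs. Per-iteration seeds derive deterministically from
the master seed, so runs are reproducible bit for bit and iterations could
be parallelized without changing results.

**Modules.** Average-linkage hierarchical clustering on $1 - S$ cut at
`cut_height` ([cluster_modules()]). The linkage is configurable; average is
the default because single linkage chains and complete linkage shatters
sparse consensus matrices. Clusters below `min_size` (default: the pruning
lower bound $m_1$) are discarded — they could never survive pruning anyway.

**Summarization.** A module is summarized by up to three components:
plain PCA of the standardized submatrix, or the topology-aware NetSHy
variant, which runs PCA on the concatenation $[X,\ X L]$ where $L$ is the
symmetric normalized graph Laplacian of the module's (max-normalized)
induced adjacency; isolated nodes get zero rows so an edgeless module
degenerates to plain PCA. Several topology operators are defensible here
(normalized Laplacian, adjacency powers, topological-overlap transforms);
ours is exposed as a named strategy
([netshy_summarize()]) so an alternative operator can be dropped in without
touching the pruner. Loading signs follow the same largest-coordinate
convention as the solver.

**Pruning.** Features are ranked by weighted PageRank (damping 0.85) on the
induced similarity graph. For each size $i \in [m_1, m_2]$ (defaults 10 and
100) the top-$i$ features are summarized and
$\rho(i,\text{pheno})$ — the best absolute component correlation with the
phenotype (point-biserial for binary) — is recorded. Then

* $m^\* $ = size maximizing $|\rho(i,\text{pheno})|$ (ties: smallest, for
  parsimony);
* $x$ = largest size in $[m^\*, m_2]$ whose summarization score keeps
  $|\rho| > 0.8$ with the size-$m^\*$ score — compared on the
  phenotype-selected component, in absolute value, since that is the only
  score the procedure carries forward;
* $m_{\text{opt}}$ = largest size in $[m^\*, x]$ retaining at least 90% of
  $|\rho(m^\*,\text{pheno})|$.

The full trace ($\rho$ sequences and all three landmarks) is returned and
persisted, and the implementation is checked against a brute-force
enumeration of the same rules on randomized fixtures.

## What the synthetic generator does (and does not) emulate

[generate_synthetic()] plants one shared Gaussian latent factor: planted
features are `loading * factor + N(0, noise_sd)`, background features are
independent standard normals, and the phenotype is `effect * factor` plus
noise (quantitative) or Bernoulli with a logistic link (binary). Defaults —
$n = 200$, two blocks of 100 features, 5 planted each, loading 1, noise sd
0.3 — are the conditions under which the package's recovery claims are
tested: the zero-noise variant for support recovery by a single SmCCA fit,
and the noisy variant for end-to-end capture of planted features by the
top-ranked module across ten seeds.

This generator produces exactly the correlation structure the model
assumes: one factor, homogeneous loadings, Gaussian margins, independent
background. Real omics data have heavy-tailed and count-valued margins,
correlated background (batch, cell composition), multiple overlapping
factors, and block-specific scales. Passing the recovery tests therefore
demonstrates correctness of the machinery, not performance on real data.

## Numerical choices and scales used

* Projection bisection: 200 iterations; constraints verified to $10^{-6}$.
  Exact ties at $c = 1$ resolve to the lowest index.
* Coordinate ascent: stop when the largest weight change falls below
  $10^{-6}$, cap at 100 sweeps (best iterate returned, flagged
  non-converged).
* PageRank: damping 0.85; computed on the weighted undirected graph;
  all-zero adjacency returns uniform scores with a warning.
* Missing values are rejected, never imputed. Coefficient-of-variation
  filtering uses the sample (n−1) standard deviation; features with mean
  exactly zero are kept (their CoV is undefined, not degenerate) with a
  warning. There is no universal CoV threshold default — it is a required
  choice per platform. Covariates are regressed out before scaling so
  scaling restores unit variance.
* Demonstration scales: the test suite and examples use $n \le 200$ and
  blocks of at most 100 features, CV with $K = 3$ folds over 1–4 grid
  points, and 8–25 subsampling iterations. These sizes were chosen as the
  smallest at which the planted structure is comfortably identifiable. One
  consequence worth repeating: on such narrow blocks the penalty fraction
  0.1 hits the single-feature floor $c_t = 1$, so desk-scale grids start at
  0.2; wide (real) blocks can use the full 0.1–0.5 default grid.

## Known limitations

Only the first canonical component is extracted; multi-class phenotypes,
time-to-event and longitudinal outcomes are out of scope, as are
imputation, batch correction and interactive visualization (module exports
— edge lists, GraphML, score and loading tables — are designed to feed
external viewers). The NetSHy operator is one defensible construction among
several. Similarity rescaling by the maximum makes cut heights comparable
across runs of the same data but not across datasets.
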