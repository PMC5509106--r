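---
title: "Methods: ancestral expression evolution and knockout prioritisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ancestral expression evolution and knockout prioritisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fruitbody)
```

# The analytical problem

Five Sordariomycete fungi — *Fusarium graminearum*, *F. verticillioides*,
*Neurospora discreta*, *N. crassa* and *N. tetrasperma* — build
morphologically comparable sexual fruiting bodies (perithecia) through five
canonical developmental stages, yet the two genera diverged on the order of
two hundred million years ago and differ in late structures such as the
*Neurospora* beak. Given stage-resolved expression profiles of single-copy
orthologs in all five species, the package asks: for which genes has the
*developmental program of expression* evolved most strongly along one
lineage, and do knockouts of those genes disrupt development at the stage
where the expression change occurred?

# Relative expression and the signed fold-change statistic

Absolute expression cannot be calibrated across species, so all analysis is
relative. A profile $X_1,\dots,X_S$ over $S$ stages is reduced to the
signed stage-to-stage statistic

$$d_t = \frac{X_{t+1} - X_t}{\min(X_t, X_{t+1})}, \qquad t = 1,\dots,S-1 .$$

A $k$-fold increase gives $d = k - 1$ and a $k$-fold decrease $-(k-1)$:
magnitudes are symmetric, the sign is the direction of change, and the
statistic is invariant to any gene-wise rescaling of the profile. The
inverse transform (`fold_change_to_profile()`) multiplies by $1 + d_t$ for
increases and divides by $1 - d_t$ for decreases, then rescales so the
lowest stage equals one; `stage_fold_change()` after the inverse is the
identity to $10^{-10}$, which the suite property-tests over random vectors
in $[-50, 50]$.

## Normalisation

The original expression estimates came from a Bayesian level-of-expression
estimator; this package deliberately uses a simple, transparent stand-in
(`normalize_counts()`): counts are scaled per sample to counts-per-million,
a pseudocount of $\varepsilon = 0.5$ scaled counts is added, replicates
within a canonical stage are combined by geometric mean, and each gene is
divided by its minimum stage value. Only relative stage-to-stage levels
feed the downstream mathematics, and the generator-based round-trip test
quantifies the stand-in's fidelity: at a depth of $10^6$ reads and low
dispersion the median per-gene maximum relative error against the
generating profile is under 5%.

Two caveats are intentional properties of relative data, not bugs. First,
library-size scaling estimates profiles only up to a per-stage
compositional factor; when many genes rise at the same stage, the realized
library composition absorbs part of the signal (the round-trip test
isolates sampling noise by fixing library sizes). Second, the pseudocount
bounds fold changes for genes touching zero counts, so every gene yields a
complete, comparable fold-change vector rather than dropping transitions.

The mapping of the eight *Neurospora* and six *Fusarium* sample points onto
the five canonical stages is not published; the shipped defaults
(8 &rarr; 1,1,2,2,3,4,5,5 and 6 &rarr; 1,2,2,3,4,5) are configuration
inputs (`default_stage_mapping()`, `map_samples_to_stages()`), not claims.

# Brownian-motion ancestral reconstruction

Each transition character $d_t$ is treated as an independent continuous
trait evolving by Brownian motion on the fixed, ultrametric species
chronogram (branch lengths in Myr). The maximum-likelihood internal-node
states minimise

$$\sum_{\text{branches}} \frac{(x_{\text{child}} - x_{\text{parent}})^2}{v_{\text{branch}}},$$

solved exactly by a two-pass pruning scheme: an upward pass collapses each
subtree into an effective value and effective branch length, and a downward
pass finalises each node given its parent. The states are independent of
the rate $\sigma^2$, invariant to rescaling all branch lengths by a common
factor (only relative time matters), and equivariant under adding a
constant to all tips — all three properties are tested exactly, and the
states are checked against an independent algebraic least-squares oracle on
random trees to $10^{-8}$. Because the solution is linear in the tip
values, `ancestral_operator()` precomputes the node-by-tip matrix once per
tree and reconstructs thousands of genes with a single matrix product.

Design choices worth making explicit:

* characters are analysed on the raw signed $d$ scale, not log scale,
  because the signed statistic is what the downstream ranking contrasts;
* the root is a free parameter (no stationary prior), the standard
  non-stationary BM treatment;
* zero-length internal branches are collapsed into polytomies before
  solving; zero-length terminal branches are an error;
* per-gene rates are estimated by REML from standardized independent
  contrasts, $\hat\sigma^2 = \sum c_i^2 / (n-1)$. Point estimates only are
  propagated: integrating over estimation uncertainty would not move the
  means on which the ranking is based;
* no cross-stage covariance is modelled; the $S-1$ characters are
  reconstructed independently.

The chronogram itself is an input. The study's calibration fixes only the
root age range (200–240 Myr; 220 used here); the crown ages shipped with
the generator (MRCA-F 50 Myr, MRCA-N 30 Myr, the *N. crassa* /
*N. tetrasperma* split 15 Myr) are package defaults, configurable and
flagged as such. Because ancestral states are invariant to time rescaling,
the ranking is insensitive to the absolute calibration.

# Ranking, priority lists and stage concordance

For two internal nodes $A$ and $B$ (by default the *Neurospora* and
*Fusarium* crown ancestors), each gene's per-transition difference is
$\Delta_t = \hat d_t(A) - \hat d_t(B)$. The largest positive $\Delta_t$ is
the gene's $A$-up score and the largest positive $-\Delta_t$ its $B$-up
score; the gene joins the directional list of whichever maximum is larger
(ties resolve to $A$-up deterministically), lists are sorted by descending
score with ties broken by gene id, and the top `floor(fraction * n)` genes
are kept (a fixed list size can override the fraction, since a published
list length need not be an exact decile). Swapping $A$ and $B$ negates
every $\Delta_t$ and exactly exchanges the two lists.

A parallel per-stage ranking (`stagewise_lists()`) contrasts the
back-transformed node profiles $\hat X_s(A) - \hat X_s(B)$ within each
stage. For shifts planted at a single transition the global
max-over-transitions statistic is the matched filter, so the stage list is
expected to track, not beat, the global list; the suite asserts that the
shift's own stage is the most enriched of the five stage lists and
recovers most of the global recall.

Concordance between expression evolution and phenotype
(`stage_concordance()`) asks whether a knockout's phenotype stage equals
the stage of the gene's largest upregulatory difference. A transition $t$
(stage $t \to t+1$) is attributed to stage $t+1$ — the stage in which the
risen expression is manifest — by default, with the $t \to t$ attribution
selectable, because either reading is defensible for phenotypes adjacent
to the transition. Only phenotypes assignable to a canonical stage
(Stage-1 … Stage-5) enter the denominator; wild-type, initiation,
asynchronous and unclassifiable calls are excluded.

# Exact enrichment statistics

`fisher_exact()` computes hypergeometric tail sums through the log-space
density, overflow-safe for large totals, with two two-sided conventions:
the point-probability rule (sum of tables at the observed margins no more
probable than the observed one — the convention of most statistical
software, and the default) and the doubling rule (twice the smaller tail,
capped at one). The suite checks it against full enumeration on every
table with small totals and against the reference implementation on random
tables.

`overlap_test()` evaluates the overlap $k$ between a ranked list of size
$K$ and an independently characterized set of size $M$ among $N$ orthologs.
Two table constructions are supported. The classical hypergeometric
partition $[[k, K-k], [M-k, N-K-M+k]]$ with the point-probability rule is
the textbook variant. The default, however, compares the two proportions
exactly as printed — $[[k, K-k], [M, N-M]]$ with the doubling rule —
because that convention reproduces published overlap statistics quoted to
two decimals (for $9/391$ vs $61/4431$ it gives $0.221$, where the
disjoint construction gives $0.109$). Which convention a published value
used is rarely stated; making both available, with the reproducing one as
the default and the difference documented here, is the package's
resolution of that ambiguity.

# Consensus Bayesian networks

Small sets of genes (at most ~15, typically 5–12) are modelled as linear
Gaussian Bayesian networks over their fold-change observations: 7
transitions for an eight-point *Neurospora* series, 5 for a six-point
*Fusarium* series, 4 for a five-stage ancestral node. With so few
observations an unregularized maximum-likelihood score is singular —
this is the central unstated difficulty of applying structure learning to
developmental series, and the package addresses it explicitly:

* the network score is a Gaussian BIC with a small ridge penalty
  ($\lambda = 10^{-3}$) on parent coefficients;
* in-degree is capped at 2 by default ("no structural constraints" is not
  statistically meaningful at $n = 4$);
* for five or fewer genes, *every* DAG under the cap is enumerated and
  scored exactly; above five, seeded random-restart hill climbing collects
  the best distinct structures encountered, and agreement with enumeration
  on four-gene problems is itself a property the suite asserts
  (top-1 agreement $\ge 95\%$ over 100 seeded trials at 200 restarts);
* the $K = 100$ highest-scoring distinct structures are averaged; an edge's
  confidence is the fraction of models containing it, and the 50% majority
  consensus keeps edges at confidence $\ge 0.5$ (inclusive: 50 of 100
  survives, 49 does not);
* an undirected edge is *conserved* when every one of the three ancestral
  consensus networks (MRCA-N, MRCA-F, MRCA-NF) contains it in either
  orientation.

Finite-sample honesty: at 4–7 observations the BIC penalty does not
reliably suppress spurious edges (a random parent beats the $\log(n)/2$
penalty for a large share of noise draws), and members of the same Markov
equivalence class are often within noise of one another. Consensus
averaging over the 100 best structures is what provides stability; single
best structures should not be over-read, and reconstructions of specific
published network figures are treated as qualitative, never asserted
edge-for-edge. The suite's chain-recovery test accordingly uses 20
observations, where the skeleton is identifiable (87% recovery), and its
empty-graph test uses exactly orthogonalized noise, for which the empty
structure is strictly optimal.

# The synthetic-data generator as study conditions

`generator_config()` fixes the simulated conditions to the study's shape:
the five-species topology
`((F.graminearum, F.verticillioides), (N.discreta, (N.crassa, N.tetrasperma)))`
on a 220-Myr ultrametric chronogram; five canonical stages (four transition
characters); per-gene BM rates log-normal with median accumulated
root-to-tip variance 1 (`rate_meanlog = log(1/root_age)`,
`rate_sdlog = 0.5`), matching the order of magnitude of observed
stage-to-stage fold changes; lineage shifts planted in 5% of genes as a +4
offset on the *Neurospora* stem branch at transition 4, inherited by the
whole clade; negative-binomial counts
($\mathrm{Var} = \mu + \alpha\mu^2$, $\alpha = 0.05$, depth $10^6$) at 8
*Neurospora* / 6 *Fusarium* sample points; and knockout phenotypes that
land in the shift's stage with probability 0.5 for planted genes while
non-planted genes are wild type with probability 0.95. Everything is
reproducible from a single seed.

The generator realises exactly the model the inference assumes (BM on the
true tree, single-transition step shifts). Passing tests therefore
demonstrate correctness of the machinery and its statistical calibration
under the model — not robustness to what real data add: rate variation
across stages, correlated characters, ortholog misassignment,
compositional library effects beyond those simulated, or non-BM evolution.
The BM identities ($\mathrm{Var}[\text{tip}] = \sigma^2 \cdot$ depth,
$\mathrm{Cov}[\text{tips}] = \sigma^2 \cdot$ shared path) are verified
empirically at $10^4$ genes.

Under these default conditions the top-decile recall of planted +4 shifts
is about 0.88 at the tested seed (the acceptance threshold is 0.8); at +5
recall rises to ~0.9–0.95 but not to 1, because the decile boundary is set
by the null maximum over four transitions, whose upper tail reaches the
planted range. Recovery analyses use a root-state spread
(`root_sd = 2`) so the regression of estimated on true root states is
identified; its slope is within $[0.9, 1.1]$ for accumulated variances
0.5–8, with RMSE increasing monotonically in the rate.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which each statistical property is stable: 1,000
genes for ranking and root-state recovery, 2,000 for rate recovery, 10,000
for the BM identities and the fold-change round trip, 100 seeded trials
for the structure-learning agreement. Floating-point TSV output is fixed
at six significant digits so reruns are digest-identical; consensus
thresholds are compared with a $10^{-9}$ slack so confidences that are
exact multiples of $1/K$ sit on the inclusive side of the boundary; ridge
regressions bound residual sums below by $10^{-12}$ before taking logs.

# Limitations

* The normalizer is a documented stand-in, not a reimplementation of the
  original Bayesian estimator; systematic differences between the two
  propagate to fold changes.
* Single-transition characters ignore cross-stage covariance; a gene whose
  whole profile shifts coherently is treated as four independent signals.
* The phenotype fixture transcribes published stage calls through an
  explicit free-text-to-class mapping; borderline descriptions
  (e.g. ascus-less walls, beak defects) are classed by the first affected
  canonical stage as stated in the source descriptions.
* Network structures at developmental-series sample sizes are hypotheses
  stabilised by consensus averaging, not identified causal graphs.
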