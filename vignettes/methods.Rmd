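---
title: "Tripartite network-based inference: model, evaluation protocol, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tripartite network-based inference: model, evaluation protocol, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triplink)
```

## The inference model

`triplink` ranks candidate associations between non-coding RNAs and
diseases on a tripartite graph $G(O, T, D, E)$: ncRNAs $O$ connect to the
molecular targets $T$ whose activity they modulate, and targets connect to
the diseases $D$ they are implicated in. The two layers are stored as
binary adjacencies $A^{OT}$ ($n \times m$) and $A^{TD}$ ($m \times p$).

The method is a two-level resource transfer. Writing $k'(x)$ for a node's
degree in the ncRNA--target layer and $k''(y)$ for its degree in the
target--disease layer, the target-level and disease-level weight matrices
are

$$
w^T_{ij} = \frac{1}{k'(t_i)^{1-\lambda_1}\,k'(t_j)^{\lambda_1}}
           \sum_{l=1}^{n} \frac{a^{OT}_{li}\,a^{OT}_{lj}}{k'(o_l)},
\qquad
w^D_{ij} = \frac{1}{k''(d_i)^{1-\lambda_2}\,k''(d_j)^{\lambda_2}}
           \sum_{l=1}^{m} \frac{a^{TD}_{li}\,a^{TD}_{lj}}{k''(t_l)}.
$$

$w^T_{ij}$ is the likelihood that an ncRNA interacting with $t_i$ also
interacts with $t_j$; it accumulates the resource of every shared ncRNA,
each splitting its unit evenly over its targets. $w^D$ does the same for
disease pairs through shared targets. The levels chain through the
adjacency into the combined weights and the score matrix:

$$
W^C = W^T \, (A^{TD} W^D), \qquad R = A^{OT} W^C .
$$

For each ncRNA the *candidate* diseases are those with no length-2 path
from it; they are ranked by descending $r_{ij}$. Known (path-connected)
pairs are excluded from every ranking.

Assumptions worth keeping in mind: edges are unweighted and treated as
equally reliable; the method uses topology only (no interaction types,
tissues, or conditions); and resource can only flow within a connected
component, which is why `recommend()` refuses disconnected input by
default (an override scores per component, with zeros across components).

## Parameters

* **$\lambda_1, \lambda_2 \in [0,1]$** (default 0.5 each): interpolate
  between neighbourhood averaging ($\lambda \to 0$; conservative, few
  confident predictions) and uniform spreading ($\lambda \to 1$; prolific).
  At $\lambda = 1$ every positive-degree column of $W^T$/$W^D$ sums to 1
  (resource conservation); at $\lambda = 0.5$ both matrices are symmetric.
  There is no universal best value — `tune_lambdas()` grid-searches them
  per dataset by cross-validated recall enhancement, which is how they
  should be chosen in practice.
* **$L$** (default 20): length of the per-ncRNA recommendation list used
  by the top-$L$ metrics.
* **$k$, repetitions** (defaults 10, 30): the cross-validation protocol.

## Numerical conventions

* Degrees of zero: $k^0$ is taken as 1 and any $1/k$ with $k = 0$
  contributes 0; the affected weight entries have empty numerator sums
  anyway, so every entry is finite and nonnegative by construction.
* Ties in ranked lists are broken by ascending disease index, making every
  ranking deterministic; identical inputs give bit-identical scores.
* Invariant checks (conservation, symmetry) use an absolute tolerance of
  1e-9; the matrix formulation agrees with a literal nested-sum
  transcription of the equations to ~1e-12 relative in the test suite.
* Matrices are dense `base` matrices: at the scales of interest
  (hundreds of nodes per class) dense BLAS products are faster and
  simpler than sparse bookkeeping, and the contract is entrywise equality
  with the equations regardless of representation.

## The cross-validation protocol

The units partitioned are the *association pairs*: all (ncRNA, disease)
pairs connected by at least one length-2 path. Each repetition randomly
splits them into $k$ folds. The training network of a fold must hide its
held-out pairs, and hiding is only possible by deleting edges. We delete,
for each held-out pair, exactly the ncRNA--target edges that would
complete a length-2 path to the held-out disease, and keep every other
edge — the *maximal no-leak* edge set. Deleting an edge can splinter off a
small fragment (a target whose only ncRNA link was deleted, together with
diseases reachable only through it); since predictions are only meaningful
on a connected network, the training network is the largest connected
component of the no-leak set. Under this construction:

* no held-out pair has a length-2 path in its training network
  (`leakage_count()` audits this structurally and the suite asserts zero);
* the training network is connected by construction. A
  resample-on-disconnect guard (up to 100 redraws per repetition) is kept
  for robustness but does not trigger under this rule.

Earlier designs we rejected: keeping only edges that support a training
pair leaves networks so fragmented at realistic sparsity that no partition
of a 10-fold repetition passes a connectivity check; hiding pairs by
deleting target--disease edges instead keeps connectivity trivially but
removes the disease-side evidence for *all* ncRNAs at once and destroys
most of the recoverable signal.

A held-out pair whose ncRNA or disease lost all its edges cannot be
ranked; such pairs are counted as `n_test_skipped` in the per-fold report
rather than silently dropped. At very low density this fraction is
substantial (an ncRNA with a single target cannot have that target's
evidence hidden and still be rankable) — an intrinsic cost of leak-free
evaluation on sparse tripartite data.

## Metrics

The protocol reports, per fold and aggregated (means over folds, with
dispersion as the SD of repetition-level means):

* **Precision/recall enhancement** $e_P(L), e_R(L)$: top-$L$ precision and
  recall on held-out pairs divided by their expectation under a uniformly
  random ranking of each ncRNA's candidates ($P_{null} = \overline{D_i/C_i}$,
  $R_{null} = \overline{\min(L, C_i)/C_i}$ with $D_i$ held-out and $C_i$
  candidate diseases). Values above 1 mean better than chance.
* **AUC**: Mann--Whitney (midrank) AUC over all candidate pairs pooled
  across ncRNAs, positives being the held-out pairs. We report the
  full-ranking AUC as primary; a top-$L$ truncated variant is available
  via `roc_auc(..., truncate_at = L)`. Pooling across ncRNAs implicitly
  compares scores between ncRNAs; per-ncRNA score scales differ with
  degree, so this AUC mixes calibration with ranking — a deliberate
  simplicity trade-off, and the reason `e_P`/`e_R` (purely within-ncRNA)
  are the primary quality metrics.
* **Recovery**: mean normalized rank $(\text{rank}-1)/(C_i-1)$ of held-out
  pairs; 0 is perfect, 0.5 is chance.
* **Personalization**: mean pairwise top-$L$ list dissimilarity
  $1 - |top_L(i) \cap top_L(j)|/L$.
* **Surprisal**: mean $\log_2(n / k_{assoc}(d))$ over recommended slots,
  where $k_{assoc}(d)$ counts ncRNAs with a known path to $d$ (floored at
  1); high values mean rarely-associated diseases are being proposed.

These are the standard recommender-system formulations of the named
metrics; the random scorer run through the same harness calibrates to
$e_P, e_R \approx 1$, AUC $\approx 0.5$, recovery $\approx 0.5$, which the
test suite checks by simulation. Two scorers are compared with the
Friedman rank-sum test (`friedman_compare()`, midranks, $\chi^2$ with one
degree of freedom) on paired per-(repetition, fold) metric values — the
finest paired unit the protocol produces; `stats::friedman.test()` is the
engine, and the all-tied case is defined as $\chi^2 = 0$, $p = 1$.

## The synthetic generator

`generate_network()` emulates the *marginal* properties of the published
benchmark compendia: node/edge counts (the `chen_like` and `helwak_like`
presets reproduce 119/110/514 nodes with 247 + 1005 edges, and
338/179/134 with 1699 + 1572), low density (directed density
$E/(N(N-1))$ of about 0.002 and 0.008, matching the reported values),
heavy-tailed degrees (preferential attachment on $(\text{degree}+1)^
{\alpha}$, $\alpha = 1$ by default), and connectedness — built by a
spanning skeleton (a random recursive tree over both node classes, then
one edge per disease) followed by preferential placement of the remaining
edges, so connectivity holds by construction rather than by rejection.
Planted structure: nodes are assigned round-robin to `n_blocks`
communities and within-block partners get their attachment weight
multiplied by `within_block_bias`; block counts of 6 (sparse regime) and
4 (dense regime) reflect the stronger vs weaker modularity of the two
real networks. Everything is fully determined by the seed.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: the joint degree structure of the real
networks, and the biological redundancy by which one ncRNA--disease
association is typically supported by several correlated targets. In a
random sparse network most association pairs have exactly one supporting
path; hiding that path for evaluation removes nearly all first-order
evidence, so cross-validated signal recovery on the sparse
(`chen_like`-scale) regime is intrinsically weak — mid-0.59s AUC under a
planted bias of 5 in our runs — while the denser regime shows clear
above-chance recovery. Real curated networks, with redundant correlated
evidence, are easier in precisely the way a marginally-matched random
network is not; conclusions about absolute real-data performance should
not be read off these synthetic benchmarks.

## Problem sizes used by the checks

The oracle-equivalence and metric-oracle tests enumerate random networks
with up to 8 nodes per class (hundreds of instances); null calibration
uses a 60/50/120-node network with 500 random-scorer replicates; the
signal-detection runs use the two full published-regime presets with
10-fold × 30-repetition cross-validation; the complexity probe fits the
operation-count slope over $m \in \{32, 64, 128, 256\}$ at fixed $p$,
where the dominant chained product $W^T(A^{TD}W^D)$ costs $m^2 p$
multiplications.

## Known limitations

* Only topology is used; interaction metadata (type, tissue, condition)
  is ignored by design.
* Scores are not comparable across ncRNAs without calibration; rankings
  are per-ncRNA.
* Leak-free hiding of held-out pairs at very low density orphans some
  test pairs (reported as skipped) and bounds how much signal any method
  can recover there.
* The generator's planted-signal contrast between biased and unbiased
  networks is small relative to network-to-network variability at
  realistic sparsity; detection claims should average over seeds.
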