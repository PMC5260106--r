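---
title: "Label propagation for drug screening: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label propagation for drug screening: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwrscreen)
```

## The model and its assumptions

`rwrscreen` treats drug screening as semi-supervised node classification on
a weighted bipartite graph. The nodes are drugs and their target proteins;
an edge carries the confidence score of the interaction. The working
assumption — and the condition under which the method can work at all — is
that drugs with a shared phenotype share target neighbourhoods, so labels
planted on a few drugs diffuse along drug–protein–drug paths to unlabeled
candidates.

Two restarting random walks run simultaneously as the two columns of

$$P(t+1) = (1-\alpha)\,T\,P(t) + \alpha L', \qquad P(0) = L',$$

with $T = D^{-1}A$ row-stochastic and $L'$ the column-normalized seed
indicator matrix (column 1: ineffective drugs; column 2: effective drugs and
optionally phenotype-associated proteins). At convergence each node is
scored by the odds $F(i) = P^*(i,2)/P^*(i,1)$ and called effective when
$F(i) > \theta$ (strict). Because $F$ is a ratio of two walks run on the
same $T$, the global scale of edge weights cancels exactly — a property the
test suite asserts for weight rescalings by 0.01 and 1000.

The iteration has the closed form $P^* = \alpha(I-(1-\alpha)T)^{-1}L'$,
which `solve_stationary_direct()` implements as an independent dense oracle
(guarded to 2000 nodes). Power iteration and oracle must agree to 1e-8;
this dual route is part of the acceptance contract and is never collapsed
onto one code path.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `alpha` | 0.5 | Restart probability per step, in (0, 1]. The source method never reports its value, so we refuse to hide a constant: it is an explicit argument everywhere, defaulting to the symmetric choice. Convergence is geometric at rate $1-\alpha$. |
| `epsilon` | 1e-9 | L1 change between iterates at which the walk is declared converged ("a very small number" is all the method states). |
| `max_iter` | 10000 | Hitting it raises an explicit non-convergence error carrying the last residual — never silent. |
| `theta` | 2 (CLI) | Screening threshold on $F$; strict inequality. F ≥ 2 is the screening rule used downstream of the original method. |
| `pseudocount` | 0 | Smoothing added to both $P^*$ columns before division. At 0 the documented policy is $0/0 \mapsto 0$ and $x/0 \mapsto +\infty$. |
| `weight_channel` | combined | Which confidence channel weighs edges. The evidence *filter* uses the experimental/database channels, but the method does not state which score weights edges; the integrated score is the natural default and the choice is exposed. |
| `min_methods` | 2 | Ortholog pairs must be supported by at least this many orthology prediction methods. |

Evidence filtering ("experimental or database support") is interpreted as a
strictly positive score in either channel — presence of an evidence type,
not a cutoff; an optional threshold argument is exposed for stricter use.
Whether filtering happens before or after ortholog mapping is unstated in
the source; the CLI defaults to filter-first and exposes
`--filter-order map-first`.

## Normalization choice

$T = D^{-1}A$ is row-stochastic, under which the column sums of $P(t)$ are
*not* conserved. We implement the iteration literally, with no per-step
renormalization: the F-ratio is a ratio of two walks on the same operator,
so the global decay largely cancels. Users expecting probability
conservation can pass `normalization = "column"` to `transition_matrix()`
to get $T = AD^{-1}$.

## Ranking and ties

Ranking is by descending F-ratio with ties broken lexicographically by node
id, so output is deterministic across platforms. Proteins receive F-ratios
too (this is what lets the method nominate phenotype-associated genes);
filtering to drugs happens at reporting time.

## The synthetic world

`generate_network()` draws a planted-partition bipartite graph: proteins are
split into modules assigned alternately to the effective and ineffective
side, and a drug of a class attaches to proteins on its side with
probability `p_within` (default 0.1) and elsewhere with `p_between`
(default 0.01). Defaults mirror a real screen's shape: positives rare
(20 effective vs 200 ineffective seeds), 100 hidden candidates split evenly,
500 proteins. Edge confidences are uniform on \[0.15, 1\] — interaction
databases publish scores above a low-confidence cutoff of about 0.15, and
the transition matrix is scale-invariant anyway, so only the spread matters.

Chemical profiles follow a symmetric location model: per-attribute class
means at $\pm$ `class_shift`/2 (so the means differ by `class_shift`) with
shared `noise_sd`; fingerprint bits are Bernoulli with logits $\pm$
`class_shift`/2. The default `class_shift = 2` gives separable but
overlapping classes — a realistic screen, not a toy. `class_shift = 0` is
the null model with no structure.

What the generator deliberately does **not** emulate: the heavy-tailed
degree distribution of real interaction databases, promiscuous hub drugs,
correlated fingerprint blocks, or batch structure in descriptors. A green
planted-recovery test therefore establishes that the implementation
propagates planted structure correctly — not that the method would achieve
the same AUPRC on any real compound collection.

If `p_between` is so small that the two planted sides disconnect, pruning
to the largest component wipes out a whole seed class; `generate_network()`
reports this as an explicit construction error rather than returning a
one-class label set that no downstream step could use.

## Numerical and policy choices

* **Duplicate interaction rows** collapse to the per-channel maximum:
  conservative, idempotent, order-independent.
* **Keep-largest-component** is the reading of "removal of small
  disconnected subnetworks": one connected network remains; ties go to the
  component containing the smallest node index.
* **Negative cosines.** Raw descriptors (e.g. xlogP) can make Eq.-(4)-style
  cosine negative. The chemical similarity matrix reports the raw value in
  $[-1,1]$ to stay faithful; values are floored at 0 only where the $[0,1]$
  contract is required — noisy-OR integration and the kNN distance. Whether
  the original work clipped or shifted is unstated; both behaviours are
  reachable (clip is the default path, shifting can be done by the caller
  before integration).
* **No descriptor standardization** is applied by default, since none is
  described; callers can z-scale before `cosine_similarity()` if desired.
* **Empty-prediction precision is 1.0** in recall–precision curves (the
  standard convention; the curve construction in the source does not state
  it), and the threshold grid is the sorted unique scores plus $-\infty$ —
  the exact curve rather than a fixed grid.
* **Cross-validation averaging.** How per-fold curves were averaged is
  unstated; both threshold-wise and recall-wise averaging are implemented,
  with recall-wise (precision interpolated as the best value at recall
  $\ge r$ on a 0.01 grid) the default.
* **Stratified folds by default.** With positives as rare as 34/450 a
  literal unstratified 5-fold split can leave a fold without positives;
  `stratified = FALSE` reproduces the literal protocol.
* **Zero-variance contrast.** If every screened drug has identical mean
  similarity to both reference sets, the paired t-statistic is undefined;
  `similarity_contrast()` returns `t = NA`, `p = 1` and an explanatory note
  instead of erroring.
* **Drugs-only cross-validation.** Whether gene seeds participated in the
  reported cross-validation is unstated (few aging genes overlap a typical
  network); `run_cv(include_genes = FALSE)` is the default and the flag is
  exposed.
* **Unlabeled network drugs** are treated as candidates only; they never
  enter gold-standard folds.

## Known limitations

* The dense oracle solver is $O(|V|^3)$ and guarded to 2000 nodes; the
  power iteration handles larger, sparse networks.
* kNN tie-breaking by drug id is deterministic but arbitrary where many
  distances are exactly equal (as happens with coarse Jaccard values on
  small target sets).
* The t-test assumes approximately normal paired differences; with planted
  Gaussian attribute structure this holds by construction, but on real
  fingerprints the test is only as good as that approximation.
* An SVM baseline, pathway enrichment, and descriptor generation from
  SMILES are out of scope by design.
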