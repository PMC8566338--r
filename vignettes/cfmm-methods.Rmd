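---
title: "Ranking essential proteins with cfmm: model and design notes"
author: "cfmm package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking essential proteins with cfmm: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfmm)
```

## The problem

Essential proteins are those whose loss is lethal to the organism. Knockout
screens that establish essentiality are slow and expensive, so a long line of
computational methods rank the proteins of a protein–protein interaction
(PPI) network by predicted essentiality, exploiting the centrality–lethality
observation (essential proteins tend to be network hubs) together with
biological annotations. `cfmm` implements one such ranking method, CFMM,
built around a collaborative-filtering view of the protein–domain network.
Its inputs are five tables of the kind curated for yeast: a PPI edge list, a
protein–Pfam-domain table, subcellular localizations over 11 compartments,
ortholog-genome counts, and a time-course expression matrix.

## The model, stage by stage

### 1. Densifying the protein–domain network

Known protein–domain interactions form a sparse bipartite 0/1 matrix
$AM_{pd}$ ($N$ proteins $\times$ $M$ domains). Sparsity is treated as a
missing-data problem and attacked with memory-based collaborative filtering,
run symmetrically from both sides.

For the protein-based pass, two proteins are similar when they share
domains:

$$SM_{PP}(i,j) = \frac{|N(p_i) \cap N(p_j)|}{\sqrt{|N(p_i)|\,|N(p_j)|}}
\quad (i \neq j), \qquad SM_{PP}(i,i) = 0,$$

a cosine similarity of binary domain profiles. The recommendation matrix is
$RM_{PD} = SM_{PP} \times AM_{pd}$, and each domain column $j$ gets a
*recommendation standard* — its column mean
$Std_j = \frac{1}{N}\sum_i RM_{PD}(i,j)$. A new edge $(k, j)$ is added
whenever $RM_{PD}(k,j) > Std_j$ strictly. The domain-based pass is the
mirror image on $AM_{dp} = AM_{pd}^T$ with per-protein-column standards.
Both passes start from the *original* adjacency and are merged by logical
OR into the mutual recommendation matrix $MRM \geq AM_{pd}$: densification
only ever adds edges. Each added edge carries provenance (protein-side,
domain-side, or both).

Two choices here were genuinely open and are fixed as follows. The
threshold is strict (`>`), so a column whose recommendations are all equal
adds nothing. The two passes are independent rather than chained, and the
whole step runs once by default (`cf_iterations = 1`); running it to a
fixed point is available but quickly saturates the matrix and is not the
intended reading of a single recommend-then-merge pipeline.

### 2. Weighting the PPI network

Each protein's row of $MRM$ is its domain-interaction profile $IP(p_i)$.
Edge weights come from the Gaussian interaction profile (GIP) kernel

$$WBP(i,j) = \exp\!\left(-\delta_p \,\|IP(p_i) - IP(p_j)\|^2\right),
\qquad
\delta_p = \delta_p' \Big/ \tfrac{1}{N}\sum_i \|IP(p_i)\|^2 ,$$

the standard normalized-bandwidth form from the GIP-kernel literature: the
raw bandwidth $\delta_p'$ (default 1) is divided by the mean squared
profile norm, which makes the kernel invariant to the overall annotation
density. $WBP \in (0,1]$, with $WBP(i,j)=1$ exactly when the profiles
coincide. The matrix used downstream is
$WP(i,j) = WBP(i,j)\,(1 + \max WBP)/2$ where the max runs over off-diagonal
entries — a single global rescale — masked to the PPI edge set, because the
propagation stage only walks along PPI edges (`mask_wp_to_ppi` behaviour,
exposed as `mask` in `wp_transform()`).

### 3. Feature scores and entropy-weight fusion

Four per-protein scores are computed:

* **ProSub** — each compartment scores its protein count divided by the
  average count over the 11 compartments; a protein sums the scores of its
  compartments. Nucleus and mitochondrion, which host the most proteins
  (and, empirically, the most essentials), score above 1.
* **ProOrt** — the count of reference genomes with an ortholog,
  max-normalized over the network.
* **ProExp** — the sum of Pearson correlations between a protein's
  expression profile and those of its PPI neighbors, floored at 0 and then
  max-normalized. The floor exists because a summed correlation can be
  negative while the entropy-weighting step below requires nonnegative
  inputs; an anti-correlated neighborhood is treated as no evidence, not
  negative evidence. Constant expression profiles get correlation 0
  (undefined correlation = no evidence).
* **ProTri** — for protein $k$,
  $\sum_{r \in NG(k)} |NG(k) \cap NG(r)| / |NG(k)|$, which equals twice the
  number of triangles through $k$ over its degree; max-normalized so it
  shares the $[0,1]$ scale of the blend below.

The three *biological* features (ProSub, ProOrt, ProExp) are min–max scaled
per column and fused with the entropy-weight method: each column is
converted to proportions $q_{kj}$ over proteins, its normalized Shannon
entropy is $e_j = -\frac{1}{\ln N}\sum_k q_{kj}\ln q_{kj}$ (with
$0\ln 0 = 0$), and the weight is $w_j \propto 1 - e_j$. A feature that is
constant across proteins has maximal entropy and weight 0 — it cannot
discriminate; if every feature is constant the weights fall back to
uniform. One entropy is computed per feature column (the standard
entropy-weight construction). The fused score blends with topology:

$$proscore(k) = \lambda \cdot proBio(k) + (1-\lambda)\cdot ProTri(k),$$

then is rescaled to sum 1 so it can serve as a restart distribution.
$\lambda = 0.65$ by default, the value selected for the DIP/Krogan-style
networks; $\lambda = 0.8$ suits smaller complex-derived networks such as
Gavin.

### 4. Propagation and ranking

The distribution-rate matrix directs mass along weighted edges toward
neighbors with high initial scores:

$$DRPM(k,r) = \frac{WP(k,r)\cdot proscore(r)}
{\sum_{i \in NG(k)} proscore(i)} \quad\text{for PPI edges, else } 0.$$

As printed this is not row-stochastic (the numerator carries $WP$), so by
default each nonzero row is additionally divided by its sum
(`normalize_rows = TRUE`); this guarantees the damped iteration

$$s^{(t+1)} = \alpha\, s^{(t)} DRPM + (1-\alpha)\, s^{(0)}$$

is an L1 contraction with factor $\le \alpha$ and converges geometrically.
The un-normalized form stays available for fidelity experiments. Scores are
row vectors multiplying $DRPM$ on the left. Iteration stops when the L2
step norm drops below $\varepsilon$ (default $10^{-6}$; cap 100
iterations); the fixed point satisfies
$s = (1-\alpha)\,s^{(0)}(I - \alpha\,DRPM)^{-1}$, which the tests verify by
a direct linear solve on small graphs. Dangling (isolated) rows simply leak
mass that the restart term replenishes; no extra dangling-node
redistribution is layered on. Defaults: $\alpha = 0.9$,
$\varepsilon = 10^{-6}$. The final ranking is by descending score with
deterministic tie-breaks (descending initial score, then protein ID).

## A worked desk example

The 5-protein, 4-domain network `toy_pdi()` is small enough to trace by
hand and anchors the test suite:

```{r toy}
toy <- toy_pdi()
toy$pdi$adjacency
cf <- run_cf(toy$pdi)
cf$rm_pd["p3", "d1"]   # 1/sqrt(2): recommend p3 to d1 (standard is 0.4414)
cf$std_pd["d1"]
cf$rm_pd["p2", "d2"]   # 0.5
cf$provenance
```

The protein-side pass recommends p3 and p4 to d1; the domain-side pass
adds (p1, d3). Merging gives the mutual recommendation matrix.

## The synthetic-data generator

`simulate_data()` produces a complete input bundle with planted essential
labels so the pipeline can be exercised and validated without any database
downloads. What it emulates, and the defaults chosen as a realistic desk
model of a yeast-scale study shrunk to $N = 300$:

* **PPI**: preferential attachment (3 edges per arriving node) with the
  attachment propensity of essential nodes multiplied by 3 — PPI degree
  distributions are heavy-tailed, and the boost plants the degree/triangle
  signal that centrality-based prediction relies on.
* **PDI**: 1–3 domains per protein; essentials draw from a small shared
  pool with probability 0.7, so their domain profiles — and hence their GIP
  kernel weights — cluster.
* **Subcellular**: the 11-compartment yeast vocabulary; essentials include
  nucleus or mitochondrion with probability 0.7, mirroring the observed
  enrichment of essentials in those compartments.
* **Orthology**: per-genome presence over 100 reference genomes, probability
  0.6 for essentials vs 0.25 otherwise.
* **Expression**: 36 time points; essentials load (loading 1.5) on a shared
  periodic latent factor plus unit Gaussian noise, others are pure noise, so
  essential-essential neighbor correlation is elevated.
* A fifth of the proteins are essential, roughly the fraction in curated
  yeast networks.

`null_effects()` zeroes every one of these contrasts, making labels
independent of all features — the negative control. The generator is
seeded and bit-reproducible: the same seed yields byte-identical files.

What the generator does **not** emulate: the literal degree distributions
of DIP/Krogan/Gavin, correlated annotation noise, systematically missing
annotations (real sources cover only part of the network), or
domain-composition realism. Passing tests on synthetic data therefore
demonstrate that the pipeline recovers the *kinds* of signal it models, at
the effect sizes planted — not that it attains any particular accuracy on
real databases.

## Evaluation conventions

Top-$k\%$ cutoffs use `ceiling(p/100 * N)` — the only rounding rule
consistent with the published cutoff pair (51, 1274) at both 1% and 25% of
5093 proteins. ROC AUC uses the Mann–Whitney statistic with midranks for
ties (identical to the trapezoid rule on the tie-grouped curve); a
brute-force pair-counting oracle and an independent ROC implementation
(pROC) cross-check it in the tests. Gold-standard proteins missing from the
ranked universe are dropped with a warning, so precision denominators are
in-network cutoffs.

## Numerical and degenerate-input choices

* Zero-degree entities get similarity 0 to everything (the 0/0 limit of the
  cosine formula) and isolated proteins get all-zero propagation rows.
* An entry exactly equal to the recommendation standard is *not* added.
* Proteins missing from an annotation source score 0 on that feature —
  with ~5,000-protein networks integrated against ~4,900- and
  6,800-protein annotation sources, gaps are unavoidable and zero is the
  conservative neutral value.
* The restart vector is normalized to sum 1, making $\varepsilon$
  scale-stable; squared-distance computations clamp tiny negative values
  from floating-point cancellation.

## Problem sizes used by the tests

The oracle-equivalence suites run on hundreds of random bipartite graphs up
to $8\times 8$ against triple-loop implementations; kernel monotonicity is
enumerated over all binary profiles up to length 6; the closed-form
propagation check solves $(I-\alpha D)^{-1}$ on graphs up to 10 nodes; and
the planted-signal check runs the full pipeline on 20 paired synthetic
datasets at $N = 300$ (default vs zero effects), comparing AUC by a paired
sign test. These sizes were chosen so every structural claim is verified
against an independent computation while the whole suite stays quick to
run.

## Known limitations

* The method ranks; it does not calibrate probabilities of essentiality.
* Collaborative-filtering densification assumes shared domains imply
  shared missing annotations; proteins with no domain annotations at all
  receive no recommendations and rely purely on topology and biology.
* The entropy-weight scheme is scale-sensitive upstream of its proportion
  step; min–max scaling is applied per feature, and a different
  normalization would shift the weights.
* With `normalize_rows = FALSE` (the literal printed propagation matrix),
  convergence is not guaranteed; the default therefore deviates from the
  literal formula in favor of a well-posed iteration, and the flag records
  that choice.
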