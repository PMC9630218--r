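---
title: "Classifying and ranking vessel-tree groupings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and ranking vessel-tree groupings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(vesselrank)
```

## The data model

`vesselrank` works on a rooted, acyclic, directed graph in which the
*edges* are vessel segments — the stretch of vessel between two
consecutive bifurcations (or between a bifurcation and a terminal tip) —
and the nodes are branch points. Segments are the atomic unit of
classification and each carries a unique positive integer ID, which is
also the link back to the imaging domain: a 3D label volume whose voxel
values are segment IDs can be relabeled by any per-segment attribute with
`remap_volume()`.

Three structural invariants are enforced at load time:

* the graph is a tree (connected, acyclic, one parent per non-root node);
* the root has out-degree 1 — trees begin just before the first
  bifurcation, so there is a single root segment;
* no internal node has total degree 2. Chains of collinear edges are
  collapsed into one segment whose length is the sum of its parts and
  whose diameter is the length-weighted mean (`collapse = FALSE` is
  available for debugging skeleton exports). Collapsing is idempotent.

Where a root cannot be inferred (undirected input, several in-degree-0
nodes) it must be named by the caller: which end of the tree faces the
hilum is an anatomical fact, not a graph property. Coordinates and lengths
are optional; every classification works on purely combinatorial trees.
All lengths and diameters are micrometres throughout; the package never
converts units.

ID attribution (`assign_ids()`) is a depth-first preorder from the root,
visiting children in ascending order of child-node name (numeric order if
all names are numeric). Any deterministic order would serve; this one is
reproducible from the input file alone.

## The four classification schemes

For a segment $e$ with child segments $c_1, \dots, c_m$:

* **generation** $g$: root segment $g = 1$; every child gets its parent's
  label plus one. Top-down; the number of groups equals the segment depth
  of the deepest leaf.
* **Horsfield order** $o$: terminal segments $o = 1$; a parent gets
  $\max_i o(c_i) + 1$. Bottom-up; the maximal order equals the maximal
  generation (both count the longest root-to-leaf path), which is why the
  two schemes can produce the same *number* of groups while partitioning
  the tree entirely differently.
* **Strahler order** $s$: terminal segments $s = 1$; a parent gets
  $s^* + 1$ if *two or more* children attain the maximal child order
  $s^*$, and $s^*$ otherwise. At a multifurcation the same "two or more"
  rule applies. Strahler order is segment-wise bounded by the Horsfield
  order, and the order-1 sets of the two schemes are identical (the
  terminal segments).
* **fractal generation** $f$: the main trunk — a root-to-leaf path — is
  labeled 1 along its entire length; every branch leaving a level-$n$
  trunk is itself a trunk labeled $n + 1$ from branching point to tip,
  recursively. The scheme partitions the edges into exactly one trunk per
  leaf.

Trunk identification is the one genuinely open design point: in practice
trunks are curated semi-manually ("the vessel centered in the lobe" is a
visual judgement). The default rule follows, at every branch point, the
child with the greatest total downstream path length (edge count when
lengths are missing), with ties broken by larger mean diameter and then by
smaller segment ID; `max_subtree_size` and `max_diameter` rules are
available, and an `overrides` argument accepts a set of segment IDs forced
onto trunks so that manual curation can be reproduced exactly. Overrides
competing for the same branch point are rejected (`"invalid trunk
override"`). Because tie-breaks consult segment IDs, fractal labels — unlike
the other three schemes — are guaranteed invariant only under
relabelings that preserve the ID assignment.

## Morphometry

Measurements arrive as per-slice rows `(segment, slice, inner diameter,
outer diameter)`; a segment crossing many sections contributes many rows.
`aggregate_measurements()` averages each segment's rows with equal weight
and derives the wall thickness from the averaged diameters,

$$h = \tfrac12\,(\bar d_\mathrm{outer} - \bar d_\mathrm{inner}),$$

which for paired rows equals the mean of per-row wall thicknesses — the
two readings of "average the measurements, halve the difference" coincide,
so the choice is immaterial for the only input format the package accepts.
Irregular slice gaps are *not* compensated by weighting; with a nominal
step of 20 µm and occasional gaps of a few slices, the induced bias is far
below measurement noise. Rows violating `0 < inner ≤ outer` are rejected
by row number. Segments without measurements stay in the tree and in every
label map but are excluded from the feature matrix; `coverage()` reports
the measured fraction (to one decimal, in percent).

## The reference clustering and the ranking

Whether a grouping is "good" is judged against the feature cloud itself.
`fit_gmm()`/`select_model()` fit Gaussian mixtures over a grid of
component counts $k = 1..9$ and six covariance families (spherical,
diagonal and full; shared or per-component) and keep the fit maximizing

$$\mathrm{BIC} = 2\log L - m\log n,$$

with $m$ the free-parameter count (weights $k-1$, means $kd$, plus the
family's covariance parameters). The maximize convention is used
throughout; the negated convention differs only by sign. Mixture fitting
is delegated to `mclust`, whose model-based hierarchical initialization
makes every fit deterministic; on top of the six standard families, any
`mclust` model code (including orientation-constrained families such as
`VVE`) is accepted. `kmax = 9` is the default scan range; raising it is
only useful when the feature cloud plausibly supports more components than
segments-per-group would suggest. Failed fits (collapsed components,
$k \ge n$) are recorded in the grid as missing, never silently dropped.

`davies_bouldin()` implements the index directly:
$S_i = (\mathrm{mean}_{x \in i}\, \lVert x - A_i \rVert_p^{\,q})^{1/q}$,
$M_{ij} = \lVert A_i - A_j \rVert_p$, and
$\mathrm{DB} = \frac1k \sum_i \max_{j \ne i} (S_i + S_j)/M_{ij}$.
Defaults are $p = q = 2$ — Euclidean separation and root-mean-square
dispersion, the convention of the established R implementation of the
index — with $q = 1$ (mean distance, common elsewhere) a configuration
away. The index is invariant under group relabeling, rigid translation
and uniform scaling of the features; the test suite checks it against a
brute-force double-loop implementation to $10^{-10}$.

Two degeneracies need policy. Groups *empty* on the measured subset (all
their segments unmeasured) are dropped from the score and counted
(`n_empty`); singletons have $S_i = 0$ by construction. Both make a scheme
look better without contributing separation, so `rank_schemes()` reports
their counts next to every score — a scheme with many near-empty groups
should be read with suspicion, not celebrated for a low index. Identical
centroids ($M_{ij} = 0$) raise an error rather than returning infinity.
Fewer than two non-empty groups is an error recorded per scheme in the
report rather than aborting the ranking.

The features clustered by default are inner diameter and wall thickness,
unscaled. Raw micrometre values keep the index interpretable in the units
the measurements were made in; because diameter spans a much wider range
than wall thickness, it dominates the Euclidean geometry, which matches
the biological reading that calibre is the primary separator of vessel
classes. `standardize = TRUE` switches to unit-variance features when the
two observables should count equally; outer diameter can be selected via
`columns =`.

## What the synthetic generator does and does not emulate

`generate_tree()` grows either a complete binary segment tree
(dichotomous) or a monopodial lobe: a trunk of `trunk` segments whose
junctions bear a lateral with probability `lateral_prob`; laterals are
shorter monopodial subtrees down to `depth` levels, single segments at the
last level. A junction without a lateral is no branch point, so the trunk
simply continues as a longer segment — generated trees always satisfy the
between-bifurcation invariant. True branch level, diameter and wall
thickness are stored per segment as ground truth so tests never re-derive
truth from noisy output.

Defaults describe a mouse-lung arterial lobe at micro-CT scale, chosen
once as a realistic operating point: a 40-segment trunk of ~150 µm
segments (a ~6 mm lobe), three branch levels (several hundred segments in
total), root diameter 150 µm halving per level so the deepest vessels sit
near the ~30 µm resolution floor of synchrotron µCT, wall thickness 8% of
diameter varying only weakly (+5% per level) with position in the
hierarchy, and mild lognormal jitter (8% diameter, 25% length).
`generate_measurements()` samples one paired measurement per 20 µm of
segment length (≈4–8 rows per segment), adds Gaussian noise of 2 µm
(about half a voxel), and drops whole segments independently with
probability 0.205 — reproducing a ~79.5% measured fraction.

Deliberate simplifications: diameters are set by *branch level* (a
Strahler-like hierarchy with a geometric shrink law), not by a hemodynamic
model; dropout is independent per segment, whereas real missingness is
spatially structured (whole misaligned stacks); there is no taper within
a segment, no measurement outliers, and no truncated distal subtrees.
Consequently, passing tests demonstrate that the workflow recovers a known
hierarchy from noisy, incomplete measurements of this structure — they do
not certify performance on real lungs, where the diameter law, the
missingness pattern and the wall composition are all less tidy.

## Numerical and testing choices

* Group labels start at 1 in every scheme; label sets and their
  cardinalities (`group_counts()`) are reported alongside scores.
* BIC comparisons use exact log-likelihoods from the fit; the $k = 1$
  case is verified against the closed-form Gaussian MLE likelihood.
* Davies-Bouldin uses no epsilon regularization; degenerate geometry is
  an error by design (see above).
* The test suite enumerates all 200 rooted tree shapes with up to 8
  segments for exhaustive Strahler verification, uses 100-replicate
  simulations (n = 400) for BIC model-count recovery, and 100 seeded
  pipeline runs (20-segment trunks, 3 levels) for the scheme-ranking
  property; these sizes make the full suite run in about a minute while
  keeping every stochastic acceptance margin (≥95/100, ≥99/100) well away
  from its threshold.
* `scripts/acceptance.R` re-runs the default-scale pipeline
  (~600–700 segments) plus the closed-form fixtures and writes all
  headline numbers as JSON.

## Limitations

* The package consumes graphs; segmentation and skeletonization quality
  is upstream and unexamined here. Prematurely truncated distal segments
  are ordinary leaves to every scheme — callers who know about truncation
  must handle it themselves.
* Orders and generations are sensitive to resolution: adding one level of
  resolvable vessels shifts every bottom-up order. Comparisons across
  datasets are only meaningful at matched resolution.
* The Davies-Bouldin index judges *this* feature pair under *this*
  metric; a scheme ranked poorly on (diameter, wall) geometry may still
  encode real biology the features do not see.
* Diameter-defined Strahler variants and asymmetry-aware order models are
  not implemented; the scheme interface (`scheme_labels`) is the
  extension point for them.
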