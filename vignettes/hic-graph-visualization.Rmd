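---
title: "Graph-based visualization of Hi-C contact maps: model and methods"
author: "HiCNets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based visualization of Hi-C contact maps: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HiCNets)
```

## The representation

A normalized Hi-C contact map is a symmetric matrix CM over N genomic
bins. HiCNets turns it into an undirected weighted graph in which every
bin is a vertex and three edge classes coexist:

* **linear** edges join bins that are adjacent along a chromosome and
  carry weight exactly 1/resolution. They encode prior biological
  knowledge — the covalent continuity of the DNA — rather than a
  measurement, and they guarantee that bins with no assayable contacts
  (condensed, repetitive centromere and telomere regions typically have
  none) remain part of the picture, attached to their chromosomal
  neighbours. For N bins on C chromosomes there are always N − C of
  them.
* **cis** and **trans** edges carry the measured interaction frequency
  CM<sub>i,j</sub> between non-adjacent same-chromosome bins and
  different-chromosome bins respectively. An optional multiplicative
  `scale` and a `minFreq` threshold are applied before edges are
  created; the defaults (1 and 0) use every positive entry unchanged,
  which is also the configuration used for all shipped analyses.

One representational question the weight rules leave open is what to do
when the map reports a contact between two bins that are *already*
joined by a backbone edge. Creating a parallel edge would make the
object a multigraph, and silently replacing the backbone weight would
destroy the structural scale. HiCNets keeps the backbone weight at
1/resolution and records the measured frequency as an auxiliary
`measured_freq` attribute; the `combine` argument of the layouts and of
`asAdjacency()` decides how the two are merged (`"sum"`, the default,
adds them so both the bond and the measured contact attract;
`"interaction_only"` uses the measurement where one exists). All edge
tables are kept in a fixed sort order so every writer in the package is
byte-deterministic.

## Layouts

### Stress majorization (edge-weighted spring analogue)

Interactive tools commonly offer an "edge-weighted spring-embedded"
layout whose exact internals are proprietary and version-dependent.
HiCNets implements the reproducible classical analogue with the same
qualitative contract — high interaction frequency pulls bins together —
as its `stressLayout()`: each edge gets target length 1/weight (so a
backbone edge has physical length = resolution, giving the chromosome
arms a scale), target distances between all pairs are weighted
shortest-path lengths, and coordinates minimize the normalized stress

$$\sigma(X) = \sum_{u<v} \frac{(\lVert x_u - x_v\rVert - d_{uv})^2}{d_{uv}^2}$$

by SMACOF majorization. The mapping 1/w (rather than, say, −log w) was
chosen because it is monotone, parameter-free and makes the 2-vertex
case exactly solvable (final distance = 1/w), which the tests exploit.
Majorization guarantees the recorded stress trace never increases; the
implementation additionally stops if floating-point rounding ever
produces a nominal increase, so the published invariant holds exactly.
Disconnected components — possible only with an aggressive `minFreq`,
since the backbone connects each chromosome and is never filtered — are
embedded independently and packed left-to-right.

### ForceAtlas2

`forceAtlas2()` implements the published force model: attraction
w<sup>δ</sup>·d along edges, repulsion k<sub>r</sub>(deg<sub>u</sub>+1)(deg<sub>v</sub>+1)/d
between all pairs, gravity of magnitude g·(deg+1) toward the layout
centroid, and the adaptive speed rule in which each vertex's step is
damped by the square root of its *swing* (the change in its force
vector between steps) and bounded, so no vertex teleports. Repulsion is
evaluated exactly in O(N²) per step: at the ~1258-bin scale of a yeast
genome a vectorized exact evaluation takes well under 0.1 s per
iteration, so the Barnes–Hut approximation (an option in the original
algorithm) is deliberately not implemented — it would add approximation
error without a measurable benefit at the genome sizes this package
targets. The run executes exactly `iterations` steps and returns the
global swing per step as its diagnostic trace; the random start is
fully determined by `seed`, making reruns byte-identical.

Reference tools' "default parameters" are version-dependent and not
recoverable; the defaults here (k<sub>r</sub> = 2, g = 1, δ = 1,
jitterTolerance = 1, 300 iterations) were chosen once for stability and
are documented, not claimed identical to any GUI's.

## Metrics

The structural claims usually read off Hi-C visualizations —
condensation, intermingling, territories — are qualitative. HiCNets
operationalizes them; these definitions are this package's own and
should be cited as such:

* `cisTransRatio(g)` = (Σ cis weights)/(Σ trans weights), a pure data
  property independent of any layout. It is invariant to frequency
  scaling (the factor cancels) and rises when chromosomes condense.
  Undefined cases are flagged with IEEE values (`Inf` for cis-only
  maps, `NaN` when there are no interaction edges) rather than errors,
  so pipelines can proceed.
* `neighborhoodMixing(layout, bins, k)` — for each vertex, the fraction
  of its k nearest layout neighbours (Euclidean; ties broken
  deterministically toward the lower bin index) lying on a different
  chromosome, averaged over vertices. k defaults to 10, a local
  neighbourhood at N ≈ 1258; the statistic is invariant to rigid
  motions and uniform scaling because it depends on distance ranks
  only. It measures *visual* intermingling — the layout-free analogue
  is the cis/trans ratio, and keeping the two separate distinguishes
  data effects from rendering effects.
* `territorySeparation(layout, bins)` = mean pairwise distance between
  chromosome centroids divided by the mean within-chromosome RMS spread
  about those centroids; scale- and isometry-invariant, larger when
  chromosomes occupy distinct regions.

## The synthetic generator

`simulateContactMap()` provides the controlled inputs for testing. Its
model: the expected cis frequency between bins at linear separation s
is c₀(1+κ)s^(−α); the expected trans frequency is t₀(1−τ)/(1+κ); each
upper-triangle entry is the expectation times independent lognormal
noise exp(N(0, σ)), then mirrored. κ (condensation) reproduces the
mitotic cis-up/trans-down contrast; τ (territory strength) interpolates
between fully mixed (0) and perfectly territorial (1) genomes.

Defaults state the world the package is demonstrated in: the three
fission-yeast chromosome lengths at 10 kb (1258 bins); α = 1, the
decay regime commonly observed in Hi-C distance-decay curves; c₀ = 1 so
adjacent-bin contacts sit near the upper end of fractional balanced
frequencies; t₀ = 0.05 with τ = 0.7, making trans contacts weak and
territorial as in interphase yeast; σ = 0.3, a moderate dispersion
(±35% typical deviation) for normalized maps. Multiplicative lognormal
noise was chosen over Poisson counts because the pipeline consumes
*normalized* (non-integer, fractional) maps; it also keeps entries
nonnegative by construction. Two presets mirror the classic
experimental contrasts: `"rad21"` (territories largely lost, globally
weaker contacts — cohesin-mutant-like) and `"mphase"` (κ = 2,
mitotic-like condensation).

What the generator does **not** emulate: the Rabl configuration
(centromere/telomere clustering), chromatin domains and structural
globules, unmappable all-zero bins, distance-dependent noise, or the
statistical texture of any real dataset. A green trend test on
synthetic maps therefore establishes that the pipeline *transmits* the
modelled organizational signal into layouts and metrics — not that it
reproduces any particular published figure.

`fitDecayExponent()` closes the loop: it regresses log mean cis
frequency on log separation and recovers α exactly in the noiseless
limit (the generator is then exactly log-linear); under lognormal noise
the log-mean shifts by a constant, leaving the slope unbiased.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open (BED convention); bin indices are
  0-based everywhere user-visible (files, edge tables); triplet files
  may be declared 1-based (`oneBased`/`--one-based`) for GEO-style
  dumps, since public matrix dumps do not state their origin.
* Dense input symmetry is enforced within 1e-9, reporting the first
  offending pair; validated matrices are then symmetrized exactly so
  downstream arithmetic is clean.
* All file writers format numbers in shortest round-trip decimal form:
  triplet and edge-list round trips are exact, and identical objects
  always produce byte-identical files.
* `iterativeBalance()` uses the symmetric iterative-correction update
  (divide by the product of relative marginals) with a
  coefficient-of-variation stopping rule, masks all-zero bins rather
  than dropping them, preserves symmetry and the zero pattern exactly,
  and rescales so the mean nonzero entry is ≤ 1. A row-then-column
  alternating scheme was rejected because it does not preserve
  symmetry. Balancing is never applied implicitly: the graph model
  expects already-normalized maps.
* Layout determinism: each layout seeds R's RNG locally (restoring the
  caller's state), so results depend only on (graph, seed, parameters).
* Degenerate cases: an edgeless graph cannot be stress-embedded
  (error); a single vertex under ForceAtlas2 sits at the origin, the
  gravity fixed point; self-interactions (diagonal) never create edges
  because a self-loop carries no layout information.

## Runtime scaling in the shipped tests

The heaviest test exercises full 1258-bin genomes. Two deliberate
runtime choices there: the stress layout is run on a `minFreq = 0.02`
sparsified graph (all-pairs Dijkstra on the otherwise complete
simulated graph dominates runtime; the backbone is unaffected and the
measured trends are data properties, not threshold artefacts), and
iteration counts are modest (30–100) since the diagnostics of interest
stabilize early. The complete pipeline at that scale runs in well under
a minute on one CPU.

## Limitations

Layouts are 2D only; the embedding is a visualization, not a 3D
structure reconstruction, and distances in it should be read through
the metrics rather than measured directly. The graph model performs no
statistical filtering of interactions (no significance model, no
observed/expected normalization, no TAD calling); `minFreq` is a
display threshold, not a significance test. Real-data workflows expect
maps already normalized by ICE/Knight–Ruiz-style balancing; the
built-in balancer is a convenience implementation of simple iterative
correction, not a replacement for the original pipelines' normalization.
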