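---
title: "Integrating signalling and metabolic map layers: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating signalling and metabolic map layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigmetmap)
```

## The problem

Comprehensive molecular maps drawn in CellDesigner come in two kinds.
Signalling atlases (such as the Atlas of Cancer Signalling Network, ACSN)
draw proteins as explicit nodes, organised into functional *modules*.
Genome-scale metabolic maps (such as ReconMap 2.0, the visual counterpart of
the Recon2.04 reconstruction) draw metabolites and reactions organised into
*subsystems*, but the catalysing enzymes exist only inside reaction
annotations and gene rules — they have no position on the canvas. Two
consequences follow: omics data keyed by gene cannot be painted onto the
metabolic layer, and the two layers cannot be linked through their common
proteins.

`sigmetmap` addresses both. It (1) flattens the model's
gene–protein–reaction (GPR) rules into a protein→reaction catalysis map,
(2) computes canvas coordinates for each catalyst in the vicinity of its
reaction without colliding with existing elements, (3) merges the resulting
proteins layer back into the metabolic map, and (4) quantifies crosstalk
between the two layers' gene-set hierarchies.

## Catalysis associations from gene rules

A GPR rule is a boolean expression over Entrez gene ids, e.g.
`(8639.1 and 26.1) or 314.2`. The boolean structure distinguishes enzyme
complexes (`and`) from isozymes (`or`), but the placement problem only needs
to know *which* proteins may act on a reaction. `parse_gpr()` therefore
flattens the rule to its deduplicated gene list (transcript suffixes `.N`
stripped) — a deliberate simplification: subunits, cofactors and
post-translational states are all treated as potential catalysts, and a note
is emitted whenever structure is discarded. Entrez ids are translated to
HUGO symbols through a user-supplied two-column table
(`read_id_mapping()`); the mapping must be single-valued and unmapped ids
are returned as diagnostics, never silently dropped. The model itself is
consumed as a plain reaction/rule TSV export rather than a binary `.mat`
file, which keeps the pipeline free of a MATLAB dependency and fully
reproducible from text inputs.

## Placing protein nodes: Voronoi + sampling + K-means

The placement procedure mirrors the geometric idea illustrated in the
figure below (conceptually):

1. **Seeds.** Every alias (visual copy of a species) contributes a seed at
   its box centre, and every reaction contributes a seed at its central
   glyph. CellDesigner does not store the glyph position; we define it as
   the midpoint between the centres of the first base reactant's and first
   base product's alias boxes, which matches CellDesigner's default glyph
   placement for two-anchor reactions. For reactions with more anchors this
   is a declared convention, not a reconstruction of the editor's exact
   rule.
2. **Voronoi cells.** The canvas is partitioned into one cell per seed —
   the region closer to that seed than to any other. Cells are computed by
   clipping the canvas rectangle against the perpendicular-bisector
   half-plane towards every other seed (Sutherland–Hodgman on convex
   polygons, O(n) per neighbour). Two properties matter: the cells *tile*
   the canvas (the tests verify the cell-area sum to a relative tolerance
   of 1e-6 and cross-check ownership against a Monte-Carlo nearest-seed
   classification of 1e5 points), and each cell is *convex*, being an
   intersection of half-planes with a rectangle.
3. **Sampling.** 100 points (`n_points`) are drawn uniformly inside each
   catalysed reaction's cell, by area-weighted fan triangulation. One
   hundred points is ample for the catalyst counts seen on genome-scale
   maps; if a reaction ever has more catalysts than points, the count is
   doubled up to `max_resample` times.
4. **Clustering.** The points are grouped into K clusters, K being the
   reaction's catalyst count, and each cluster centroid becomes the centre
   of one placed protein node. Convexity of the cell guarantees the
   centroids lie inside it — hence closer to their own reaction's glyph
   than to any existing element, which is the non-overlap guarantee the
   whole construction exists for. K-means uses k-means++ seeding from the
   package's own generator with 10 restarts (best within-cluster sum of
   squares kept, ties to the first found); Lloyd iterations are delegated
   to `stats::kmeans`. The degenerate ends are exact: K = 1 returns the
   arithmetic mean, K = n returns the points.

### Determinism and numerical choices

* A single generator, seeded from `placement_config(rng_seed=)`, is
  consumed in sorted reaction-id order; identical inputs give bit-identical
  results. The geometric helpers consume R's global RNG (idiomatic in R
  rather than threading an explicit generator object); `place_proteins()`
  saves and restores the caller's RNG state.
* Coincident seed locations (two aliases drawn at the same point, or
  stacked reaction glyphs) would break the tessellation; they are separated
  by a deterministic golden-angle spiral jitter of 1e-3 canvas units —
  visually invisible, geometrically sufficient.
* The sampling region of each reaction is additionally inset from the
  canvas border by half the protein box size (default 80×40), so created
  alias boxes always satisfy the canvas-containment invariant without
  moving centres off their centroids. If the inset empties a cell (a glyph
  hugging the border), the full cell is used and the box clamped.
* Coordinates are serialised with 17 significant digits (`%.17g`), so every
  double survives a write/parse cycle bit-exactly.
* Protein boxes may overlap *each other* around a dense reaction — only
  centre containment is guaranteed. Grouping protein families into generic
  nodes would reduce the clutter but conflates family members with distinct
  functions, so each protein is kept as an independent node.

### Naming repeated proteins

A protein catalysing several reactions is placed once per reaction. Each
placed instance becomes its own species/alias pair in the overlay map, and
repeated symbols follow the CellDesigner apostrophe convention: the k-th
occurrence (k ≥ 2) of a symbol carries k−1 trailing apostrophes (`GCK`,
`GCK'`, `GCK''`, …), assigned in sorted reaction-id order. The base symbol
is preserved in each instance's `Identifiers` annotation, so data keyed by
gene symbol can still find every copy. Counting conventions follow from
this: *proteins placed* counts distinct symbols, *aliases created* counts
instances.

## Merging layers

`merge_maps()` implements classic map-merge semantics: every entity, alias
and reaction of both inputs is kept, with fresh sequential ids
(`s<N>`/`sa<N>`/`re<N>`), while names, coordinates (bit-exact) and
annotations pass through untouched. Same-named species are deliberately
*not* unified — the integrated resource links layers by shared protein
names downstream, and a silent union would destroy the one-instance-per
-placement bookkeeping above. The merge report records the id remapping and
before/after counts, and the after-counts are always the sums.

## Crosstalk between the layers

Both layers come with a gene-set hierarchy in GMT format: signalling
modules on one side, metabolic subsystems on the other.

* `shared_proteins()` intersects the two layers' symbol unions: the common
  players through which the maps are interconnected.
* `enrich()` tests each gene set for over-representation of the shared
  proteins with the upper-tail hypergeometric probability
  `P[X >= overlap]`, population = the union of both layers' proteins,
  restricted to sets with at least `min_size` (default 10) genes, with
  Bonferroni correction over the number of sets actually tested in that
  collection. The multiplicity is per collection (modules and subsystems
  corrected separately), since the two families of hypotheses are
  interpreted separately; this is a declared choice.
* `build_crosstalk_network()` connects a module and a subsystem whenever
  they share at least one shared protein, edge weight = intersection size
  (drawn proportionally in the usual visualisations). `crosstalk_igraph()`
  hands the network to igraph for degrees, components and the like.
* `reaction_regulation_counts()` counts, per module-subsystem pair, the
  distinct subsystem reactions having at least one catalyst in
  module ∩ shared (a reaction counts once however many of its catalysts
  qualify). Each reaction must be assigned to exactly one subsystem;
  multi-assignments are rejected at load because they would double-count.

## The synthetic test world

`generate_synthetic_bundle()` builds a miniature, fully-specified instance
of the whole problem: metabolite aliases on a jittered grid (so seeds are
distinct by construction), reactions joining random metabolite pairs with
1–3 (small preset) or 1–5 (dense preset, 20 reactions) catalysts drawn from
a reserved synthetic Entrez range (9,000,000+, so no collision with real
ids is possible), GPR strings exercising `and`/`or`/parentheses, a matching
id mapping, a subsystem layer derived from the reactions, and a module
layer containing a controllable fraction (`shared_fraction`, default 0.5)
of the catalysts plus signalling-only genes. The generator also emits
ground truth — per-reaction catalyst lists, glyph positions recomputed
directly from the generated geometry, the shared-protein list, and expected
crosstalk edge weights from an exhaustive double loop — against which the
pipeline is tested end to end.

What the generator does *not* emulate, and the tests therefore cannot
show: the visual conventions of hand-drawn maps (compartments, complexes,
state variables — carried only as far as parsing simple species), hub
metabolites shared by hundreds of reactions, multi-anchor reactions, and
the extreme catalyst counts (40+) of real protein families. Passing tests
demonstrate the geometric and statistical contracts, not cartographic
quality on a real atlas.

Default problem sizes in the test-suite and in `scripts/acceptance.R` (the
dense preset: 16 metabolites, 20 reactions, ≤5 catalysts; 50 random Voronoi
configurations; exhaustive enrichment enumeration up to universe 25) keep a
full run in the tens of seconds while still exercising every code path;
they are scaled-down study conditions, with the full-scale map counts
checked separately when the public map files are available locally.

## Known limitations

* Only simple protein species are created; complexes and post-translational
  states are out of scope.
* The glyph-position rule for reactions with added reactants or more than
  two anchors is a declared stand-in (first reactant / first product
  midpoint).
* Boolean GPR semantics are flattened; do not use the catalysis map for
  flux modelling.
* Enrichment assumes pre-normalised HUGO symbols in all inputs; no alias or
  withdrawn-symbol resolution is attempted, and symbol matching is
  case-sensitive throughout.
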