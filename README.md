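# sigmetmap

Integration of signalling and metabolic network maps drawn in
CellDesigner: placing the catalysing proteins of a genome-scale metabolic
map onto its canvas, merging the resulting proteins layer back into the
map, and quantifying the crosstalk between a signalling atlas and the
metabolic map through their shared proteins.

## The scientific problem

Two families of comprehensive molecular maps exist side by side.
Signalling atlases (e.g. the Atlas of Cancer Signalling Network, ACSN)
draw proteins explicitly and organise them into functional *modules*.
Genome-scale metabolic maps (e.g. ReconMap 2.0, the visual layout of the
Recon2.04 reconstruction) draw metabolites and reactions organised into
*subsystems* — but the enzymes live only in gene–protein–reaction (GPR)
rules and reaction annotations, with no position on the canvas. As a
result, gene-keyed omics data cannot be visualised on the metabolic
layer, and the two map families cannot be linked through the proteins
they share.

`sigmetmap` is aimed at computational biologists curating or analysing
such maps. It provides:

* **CellDesigner I/O** — parse and write CellDesigner-flavoured SBML with
  species/alias geometry, base reactants/products and NaviCell-style
  notes annotations, bit-exactly round-trippable.
* **Gene associations** — flatten GPR rules to protein→reaction catalysis
  maps, with Entrez→HUGO translation.
* **Placement** — compute coordinates for every catalyst near its
  reaction without colliding with existing map elements.
* **Merge** — combine the generated proteins layer with the original map,
  preserving all geometry.
* **Crosstalk** — shared proteins between two layers, hypergeometric
  enrichment of the shared set in each module/subsystem, and the
  module↔subsystem crosstalk network.
* **Synthetic maps** — a generator of fully-specified miniature problem
  instances with ground truth, used throughout the test-suite.
* **CLI** — an `exec/sigmetmap` script exposing each stage and a
  one-command pipeline.

## The placement algorithm

Let the map occupy the canvas rectangle *C*, and let the seed set
*S* = {s₁, …, sₙ} contain the centre of every species alias box plus the
central glyph of every reaction (the glyph is taken as the midpoint of
the first base reactant's and first base product's alias centres). For a
reaction *r* with glyph seed s_r and catalyst set G_r (from the flattened
GPR rule), the algorithm is:

1. Compute the Voronoi cell of every seed clipped to *C*:
   V(sᵢ) = { p ∈ C : ‖p − sᵢ‖ ≤ ‖p − sⱼ‖ ∀ j } — by successive
   half-plane clipping of the canvas polygon against each perpendicular
   bisector, so each cell is a convex polygon and the cells tile *C*.
2. Draw N = 100 points uniformly from V(s_r) (area-weighted fan
   triangulation).
3. Cluster the points into K = |G_r| groups by K-means (k-means++
   seeding, 10 restarts, Lloyd iterations) and place one protein node at
   each cluster centroid.

Because V(s_r) is convex, every centroid lies inside it and is therefore
closer to its own reaction's glyph than to any pre-existing element —
placed proteins never land on top of the drawn map. A protein catalysing
k reactions is placed k times; repeated symbols follow the CellDesigner
apostrophe convention (`GCK`, `GCK'`, `GCK''`, …) with the base symbol
kept in each instance's `Identifiers` annotation.

Crosstalk between a module collection *A* and a subsystem collection *B*
uses the shared set H = (∪A) ∩ (∪B); each set of size m in universe
N = |∪A ∪ ∪B| with overlap v against the query of size q is scored by the
hypergeometric upper tail P[X ≥ v], Bonferroni-corrected per collection.
Module–subsystem edges carry weight |a ∩ b ∩ H|.

Full method details, parameter rationale and known limitations are in the
vignette source, `vignettes/map-integration.Rmd`.

## Worked example

```r
library(sigmetmap)

bundle <- generate_synthetic_bundle(synth_preset("dense", rng_seed = 42))
bundle$map
#> CellDesigner map document
#>   canvas:    1600 x 1200
#>   entities:  16  (proteins 0, metabolites 16, other 0)
#>   aliases:   16
#>   reactions: 20

prmap <- build_protein_reaction_map(bundle$rules, bundle$idmap)
#> note: boolean GPR structure (and/or) is flattened; complex vs isozyme
#> semantics are not preserved
prmap
#> protein-reaction catalysis map
#>   reactions with catalysts: 20
#>   distinct proteins:        43

res <- place_proteins(bundle$map, prmap, placement_config(rng_seed = 42))
res$stats
#> $proteins_placed
#> [1] 43
#> $aliases_created
#> [1] 62
#> $reactions_processed
#> [1] 20
#> $reactions_skipped
#> [1] 0

head(res$placed[, c("reaction_id", "symbol", "display_name", "x", "y")])
#>   reaction_id  symbol display_name         x        y
#> 1         re1 SYNP042      SYNP042 1513.6874 614.9128
#> 2         re1 SYNP058      SYNP058 1251.6295 614.2268
#> 3         re1 SYNP097      SYNP097 1384.6973 597.4649
#> 4        re10 SYNP018      SYNP018  970.6548 289.2223
#> 5        re11 SYNP018     SYNP018'  415.3570 649.7329
#> 6        re11 SYNP042     SYNP042'  441.4490 882.4074

merged <- merge_maps(bundle$map, placement_to_map(res, bundle$map$canvas))
str(merged$report$counts)
#> List of 2
#>  $ before:List of 3
#>   ..$ entities : int [1:2] 16 62
#>   ..$ aliases  : int [1:2] 16 62
#>   ..$ reactions: int [1:2] 20 0
#>  $ after :List of 3
#>   ..$ entities : int 78
#>   ..$ aliases  : int 78
#>   ..$ reactions: int 20
write_map(merged$doc, "merged.xml")   # open in CellDesigner / NaviCell

ct <- run_crosstalk(bundle$gmt_a, bundle$gmt_b, min_size = 1)
length(ct$shared)
#> [1] 22
head(ct$network$edges)
#>    source  target weight                          shared_symbols
#> 1 MODULE1 SUBSYS1      1                                 SYNP018
#> 2 MODULE1 SUBSYS2      5 SYNP018,SYNP055,SYNP063,SYNP084,SYNP091
#> 3 MODULE1 SUBSYS3      1                                 SYNP018
#> 4 MODULE2 SUBSYS1      3                 SYNP058,SYNP085,SYNP097
#> 5 MODULE2 SUBSYS2      3                 SYNP001,SYNP026,SYNP058
#> 6 MODULE2 SUBSYS3      2                         SYNP058,SYNP069

head(ct$enrichment_a)
#>   set_name overlap_count set_size query_size universe_size    p_value
#> 2  MODULE2             6        8         22            51 0.05584247
#> 3  MODULE3             6        8         22            51 0.05584247
#> 1  MODULE1             5        7         22            51 0.11251059
#> 4  MODULE4             5        7         22            51 0.11251059
#>   p_adjusted significant
#> 2  0.2233699       FALSE
#> 3  0.2233699       FALSE
#> 1  0.4500424       FALSE
#> 4  0.4500424       FALSE
```

The same run from the shell:

```sh
exec/sigmetmap pipeline --preset dense --seed 42 --min-size 1 --out-dir run/
```

which writes `proteins.xml`, `merged.xml`, `placements.tsv`,
`network.txt`/`network.sif`, the two enrichment tables,
`regulation_counts.tsv` and `report.json`. Reruns with the same seed are
byte-identical.

## License

MIT — see `LICENSE`.
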