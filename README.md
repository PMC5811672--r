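# cellmapr

Protein–protein interaction (PPI) networks drawn **inside the cell**.

Generic graph layouts turn hub proteins — proteins with hundreds of
interaction partners — into unreadable "hairballs". cellmapr lays a PPI
network out on a biologically meaningful dimension instead: each protein is
drawn as a colored circle at a seeded-random point inside the polygonal
cell compartment (nucleus, cytoplasm, vacuole, …) it is annotated to, on
top of a cell image, with interaction edges and experimental reliability
scores overlaid. Whether a hub's partners cluster in one compartment or
span several becomes visible at a glance.

The package is headless and fully scriptable: it is aimed at
bioinformaticians who want localization-constrained PPI figures from R
scripts or shell pipelines, and at tool builders who need a validated,
deterministic reference for this visualization style.

## What it does

- **Protein document database** (JSON): per-protein records with UniProt
  accession, gene/protein names, an *ordered* localization array (the first
  entry is the primary localization) and interaction partners with optional
  reliability scores in [0, 1]. Schema in `inst/extdata/`.
- **Cell maps** (GeoJSON dialect, pixel coordinates): named polygonal
  regions of interest (ROIs) over a cell image; validation, strict-interior
  point containment, and exactly-uniform rejection sampling inside any ROI.
- **Deterministic coloring**: hue = FNV-1a(compartment name) mod 360 —
  the same compartment gets the same color on every map, in every process.
- **Two viewer modes**: *map mode* shows a circle in every annotated
  compartment; *PPI mode* shows one circle at the first (or a user-chosen)
  localization.
- **Edge overlays**: focal ego-networks and the global network among all
  loaded proteins; undirected, symmetrized, reliability-labeled.
- **Search**: case-insensitive substring search over accession, gene and
  protein names, with compartment-chip filtering and partner counts.
- **Rendering**: layered, byte-deterministic SVG; PNG export; a synthetic
  fixture generator so everything runs without external data.

## Worked example: a 12-partner hub

```r
library(cellmapr)

map <- make_synthetic_map(6, seed = 1)    # 6 disjoint compartment polygons
db  <- make_synthetic_db(50, map, seed = 2, hub_degree = 12)
map
#> <cellmap 800 x 600 px, 6 ROI(s), blank canvas>

# search, with localization chips and partner counts
res <- search_proteins(db, "gene001")
head(res[, c("uniprot_id", "matched_field", "partner_count", "border_color")], 3)
#>   uniprot_id matched_field partner_count border_color
#> 1     P00010     gene_name             3      #8cd742
#> 2     P00011     gene_name             2         <NA>
#> 3     P00012     gene_name             1         <NA>
```

`border_color` is set only for proteins annotated in exactly one
compartment — it is that compartment's hash color, ready to paint a result
box border with. `NA` means the protein is multi-localized.

```r
# the hub and its direct partners, placed at their primary localizations
nb <- neighborhood(db, "HUB00001")
length(nb$records)
#> [1] 13
placement <- place_proteins(nb$records, map, mode = "ppi", seed = 7)
head(placement$placed[, c("uniprot_id", "compartment", "x", "y", "fill")], 3)
#>          uniprot_id compartment        x        y    fill
#> HUB00001   HUB00001          er 340.6866 436.3602 #d74296
#> P00041       P00041     vacuole 578.6227 112.9275 #d742be
#> P00024       P00024     vacuole 590.7085 148.4756 #d742be

edges <- edges_for_focal(placement$placed, db, "HUB00001")
nrow(edges); head(edges$score_label, 3)
#> [1] 12
#> [1] "0.63" "0.80" "0.70"

scene <- render_scene(map, placement$placed, edges, render_options(show_rois = TRUE))
scene
#> <cellmap_scene 800 x 600 px: 13 circle(s), 12 edge(s)>
write_svg(scene, "hub.svg")        # byte-identical across runs
export_png(scene, "hub.png")
```

Each circle's fill is its compartment's deterministic color (vacuole is
always `#d742be`); edge labels are the interactions' reliability scores.
Re-running with the same seed reproduces the figure byte-for-byte, and
adding another protein to the scene does not move the existing circles
(positions come from per-protein RNG substreams).

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "cellmap.R", package = "cellmapr"))')
Rscript $CLI fixtures --out-dir demo --n-proteins 100 --hub-degree 20 --seed 1
Rscript $CLI validate --db demo/synthetic-proteins.json
Rscript $CLI search   --db demo/synthetic-proteins.json --query gene00 --compartment nucleus
Rscript $CLI render   --map demo/synthetic.cellmap.geojson --db demo/synthetic-proteins.json \
                      --proteins HUB00001,P00002,P00003 --mode ppi --focal HUB00001 \
                      --seed 7 --show-rois --out hub.svg
```

## Documentation

The methods vignette (`vignettes/cellmap-visualization.Rmd`) describes the
data model, the geometry (winding-number containment with
boundary-outside semantics, rejection sampling and its budget), the
coloring scheme and its collision behavior, the viewer-mode rules including
fallback and override semantics, rendering determinism, and what the
synthetic fixtures do and do not emulate.
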