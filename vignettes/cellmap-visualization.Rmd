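---
title: "Visualizing protein interactions inside the cell: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visualizing protein interactions inside the cell: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellmapr)
```

## The problem

Protein–protein interaction (PPI) networks drawn with generic graph layouts
degenerate into "hairballs" around hub proteins: a protein with hundreds of
partners produces a tangle in which no biology is visible. One way to
recover meaning is to lay the network out on a biologically relevant
dimension instead of edge forces: subcellular localization. Each protein is
drawn inside the cell compartment it is annotated to, on top of a cartoon
of a cell, so that at a glance one sees *where* a hub's partners live —
whether an interaction is plausible within one compartment or spans
several.

cellmapr is a headless implementation of that idea: a protein document
database, polygonal compartment maps, deterministic compartment coloring,
seeded placement, edge overlays, search, and SVG/PNG export, all scriptable
and fully testable offline.

## Data model

A protein is one JSON document: accession, primary gene and protein names,
an ordered array of interaction partners (each with an optional
experimental reliability score in $[0,1]$) and an **ordered** array of
localization annotations. The order of localizations is semantic: the first
entry is the protein's primary localization, and the single-location viewer
uses it by default. Two design points deserve justification:

* **Absent score ≠ zero score.** An interaction without a score is an
  *unlabeled* edge — the evidence simply carries no number — and is drawn
  without a label, whereas a score of 0 would be a (terrible) measurement.
  The two must survive round-trips distinctly, so the score key is simply
  omitted for unscored edges.
* **Timestamps are carried, never interpreted.** The document model
  includes creation/update stamps because real instances have them; no
  operation consumes them, so the package treats them as opaque validated
  strings.

Compartment names are user-authored free text on both sides (annotations
and map polygons), so every comparison is case-insensitive after trimming.

## Cell maps and geometry

A map is a raster cell image (or a blank canvas) plus named polygons
("regions of interest", ROIs) in image pixel coordinates — origin top-left,
y down, matching raster conventions. The file format is a GeoJSON
FeatureCollection dialect with a foreign `image` member; coordinates are
declared to be pixel-space y-down rather than geographic y-up (see the
format note shipped in `inst/extdata/`).

**Containment** uses the winding-number algorithm, with points on the
boundary counted as *outside*: a circle centered on a border would visually
straddle two compartments, which is exactly the ambiguity this tool exists
to avoid. The test suite checks the winding-number implementation against
an independently written ray-casting (crossing-number) oracle on $10^5$
random point/polygon pairs — two genuinely different algorithms that must
agree everywhere.

**Placement sampling** is plain rejection sampling from the polygon's
bounding box, which is exactly uniform over the polygon area by
construction. A budget of 10,000 attempts per requested point turns a
pathological sliver polygon (tiny area-to-bounding-box ratio) into a clear
error naming the compartment rather than a hang. Uniformity is verified two
ways: a $\chi^2$ goodness-of-fit test on a $10\times10$ grid over a
rectangular ROI (10,000 samples, $\alpha = 0.001$), and arm proportions of
an L-shaped polygon within $3\sigma$ binomial bounds. Whether the original
web tool samples uniformly is not documented anywhere we could find;
uniform is this package's own choice, stated as such.

When several polygons share one compartment name, one polygon is first
chosen with probability proportional to its area and a point is then drawn
inside it — this keeps the distribution uniform over the compartment's
*total* extent rather than oversampling small polygons.

## Deterministic coloring

Each compartment's color derives from the 32-bit FNV-1a hash of its
normalized (trimmed, lower-cased) name: hue $=$ hash mod 360, saturation
0.65, lightness 0.55 for fills and 0.35 for borders. FNV-1a was chosen
because it is a pure byte-wise integer recurrence — trivially
re-implementable as an independent test oracle, bit-identical across
platforms and locales. The hash arithmetic is done in doubles with a 16-bit
split multiply so the full unsigned 32-bit range stays exact in R.

"Unique color per compartment" must be read as *deterministic per name*,
not collision-free: 360 hue degrees cannot injectively host an unbounded
name space. Over the package's 12-name fixture vocabulary, 64 of the 66
hue pairs differ by at least 5°; two pairs happen to land close
(nucleus/mitochondrion, vacuole/membrane). That is the price of a fixed
hash and is frozen into the tests rather than patched around.

## Viewer modes

* **Map mode** shows *all* reported localizations of a protein at once: one
  circle per localization whose compartment has an ROI on the current map,
  in annotation order. Localizations without an ROI are reported as skipped
  — never silently dropped, so `placed + skipped` always accounts for every
  annotation.
* **PPI mode** shows exactly *one* location: by default the first
  localization in the array. Two decisions fill gaps the happy path leaves
  open:
  * If the first localization has no ROI on this map, placement advances to
    the next annotated localization in array order. Showing nothing would
    hide the protein entirely; the fallback keeps it visible while the skip
    report still tells the user their primary compartment is missing from
    the map.
  * A user override (re-locating the protein to another of its annotated
    compartments) must name an annotated compartment — anything else is an
    error — and does **not** fall back if that compartment lacks an ROI:
    an explicit choice should fail loudly rather than be silently replaced.

Positions are drawn from a per-protein RNG substream derived from the
global seed and the accession hash, so loading one more protein into a
scene never reshuffles the circles already placed, and placing a subset of
proteins reproduces exactly the positions they had in the full set. Circles
may overlap; no collision avoidance is attempted.

## Edges

Interactions may be stored one-sided (A lists B, B does not list A); edges
are undirected and symmetrized, each unordered pair drawn once. In focal
(ego-network) mode, one edge connects the protein of interest to each
placed partner; the partner's reliability score, when present, is formatted
to two decimals as the edge label. A multi-localized protein anchors all
its edges at its *first* placed circle — the alternative (edges to every
copy) multiplies a 338-partner hub's clutter by the number of
localizations. Edge labels sit at the edge midpoint with a white halo;
dense hub neighborhoods overplot them, which is a known open problem of
this visualization style, so a `score_label_min` threshold lets users label
only high-confidence edges.

## Rendering

SVG is the canonical output: text, inspectable, diffable, and — because the
package writes it itself with fixed two-decimal coordinate formatting —
byte-identical for identical inputs, which the tests assert literally.
Layer order is fixed: base image, ROI polygons, edges, circles, labels.
Zoom is uniform output scaling (the `scale` option changes the emitted
width/height while the viewBox keeps model coordinates). Base-image opacity
is plumbed verbatim onto the `<image>` element. PNG export draws the same
scene description through R's raster graphics device at canvas size ×
scale, so element counts and geometry agree with the SVG by construction;
PNG base images are supported for raster export (SVG embedding also accepts
JPEG). Protein labels default to off — mirroring the interactive original,
where identifiers appear only on mouse-over — with `show_labels` to opt in.

## Synthetic fixtures

The generator emulates the *shape* of a real deployment — a hand-drawn
cell cartoon with polygonal compartments and a proteome-scale document
store with reliability-scored interactions — not its content:

* Maps: up to 12 pairwise-disjoint polygons (disjoint by construction: one
  polygon per grid cell with an 8% margin) on an 800×600 canvas, cycling
  through convex blobs, concave star shapes and L-shapes. Star polygons use
  regular angles with bounded jitter, which keeps every angular gap below
  $\pi$ and therefore guarantees simplicity for any radii.
* Databases: accessions `P00001…`, localizations drawn from the map's
  compartments (30% of records multi-localized with 2–4 compartments, a
  value chosen once as typical of localization annotation databases), a
  sparse background interactome of 0–3 partners per protein with scores
  uniform on $[0,1]$ and a fifth of edges unscored, stored one-sided at
  random to exercise symmetrization. An optional hub record `HUB00001`
  lists exactly `hub_degree` partners (scores uniform on $[0.5, 1]$), all
  present in the database — the validation scenario uses degree 338, the
  size of a well-known heat-shock-protein hub.
* Timestamps are fixed so writes are byte-stable.

What the fixtures do **not** emulate: realistic proteome statistics
(degree distributions, annotation biases), real compartment geometry, or
any actual public database content. Passing tests therefore demonstrate the
geometric, combinatorial and serialization contracts, not biological
fidelity of any particular instance.

## Problem sizes and numerical choices

Validation runs at the following sizes, chosen to make the statistical
checks decisive while keeping the full suite under a minute: $10^5$
point/polygon pairs for the containment oracle; 10,000 samples per ROI for
uniformity; 200 random record/map fixtures for the viewer contracts; 100
random databases (n ≤ 50) for the edge oracle; 1,000 database/query pairs
for the search oracle; one 400-protein database with a 338-partner hub for
the end-to-end scenario.

Geometric predicates use an absolute epsilon of $10^{-9}$ (scaled by
coordinate magnitude for the boundary test) — pixel coordinates are
$O(10^3)$, so this is far below half a pixel while absorbing
double-rounding. Polygon validation requires ≥ 3 vertices, nonzero area and
simplicity (checked by $O(n^2)$ proper-intersection tests; ROI polygons are
small). JSON is written with 17 significant digits so reliability scores
round-trip bit-exactly.

## Limitations

* No force-directed or constrained layout: position within a compartment is
  random by design, so distances between circles carry no meaning.
* Edge-label overplotting in dense neighborhoods is mitigated only by the
  score threshold.
* Hue collisions between compartment names are possible and accepted;
  there is no manual color override.
* The renderer is static: no interactivity, tiling or pan/zoom.
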