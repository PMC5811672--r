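# Cell-map file format (`*.cellmap.geojson`)

A cell map is a GeoJSON FeatureCollection dialect:

- One `Polygon` feature per region of interest (ROI), carrying
  `properties.compartment` — the compartment name the polygon delimits.
  Several features may share a compartment name; placement then samples
  across them proportionally to polygon area.
- A foreign member `image` at the top level: `{"path": <string|null>,
  "width": <px>, "height": <px>}`. `path` may be `null`, meaning the scene
  is rendered on a blank white canvas of the declared size.

Deviations from strict GeoJSON, by design:

- **Coordinates are image pixel space**: origin at the top-left of the base
  image, x right, y *down* — matching raster images rather than GeoJSON's
  geographic y-up convention. No CRS member is used.
- Polygon rings are written closed (first vertex repeated last) per GeoJSON;
  holes are not supported. Winding direction is ignored (containment is
  winding-agnostic).

Validation on load: every polygon must have at least 3 distinct vertices,
nonzero area, no self-intersections, and all vertices inside
`[0, width] x [0, height]`.
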