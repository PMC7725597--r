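---
title: "Annotating time-lapse movies: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating time-lapse movies: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annotrack)
```

## The annotation model

`annotrack` turns a handful of landmark positions into a per-frame
annotation in three stages.

**Click fusion by the component-wise median.** A user labeling a moving
structure will sometimes click in the wrong place. Rather than forcing
them to edit a point list, the fusion step takes, on each labeled frame,
the median of the clicked x values and the median of the clicked y values.
A median is determined by the majority of its inputs, so k stray clicks
are neutralized by k + 1 clicks at the right position — the practical
recipe is simply "click again, twice". With an even number of clicks each
component is the mean of the two middle values, the conventional
definition.

The median is taken per coordinate rather than as a geometric (spatial)
median. The component-wise form is order-independent, exactly reproduces
the majority-override arithmetic above, and is what `stats::median` gives;
a geometric median would behave nearly identically for the clustered
clicks this workflow produces but has no closed form. Since the trajectory
file stores only positions, files produced under either convention
interoperate.

**Piecewise-linear interpolation.** The fused keyframes are connected by
linear segments, evaluated at every integer frame from the first to the
last labeled frame — never beyond either end, and a single labeled frame
yields a single-entry trajectory. Interpolation passes through *every*
keyframe (not a single first-to-last chord); this is what makes iterative
refinement work: wherever the motion bends, the user adds a click and
re-interpolates. The model is exact for piecewise-constant-velocity
motion, which covers stationary structures (velocity zero) and steady
migration or flow. Motion that curves between labels is approximated by
chords; the remedy is more labels, not a heavier model — smoothing,
splines and tracking are deliberately out of scope, and trajectories from
other software can be imported through the text format instead.

**Symbols, overlay, flatten.** A symbol specification is turned into
geometry once, then rigidly placed at each trajectory anchor. All
renderable items live in an overlay separate from the pixels; `flatten()`
is the single destructive step, after which the movie is saved.

## Symbol geometry conventions

Glyphs are built in a local frame with the **tip at the origin** and the
shaft extending toward +x, so the symbol points along −x. Placement maps
local vertices by `R(angle)·v + anchor + (dx, dy)`: rotation is about the
tip, so the symbol pivots around the point it indicates, and the tip lands
exactly on the (offset) anchor. On screen, where y grows downward, a
positive angle turns the glyph clockwise — which is counterclockwise in
conventional mathematical axes. Tip anchoring and tip-pivot rotation are
conventions chosen here; they make `dx`/`dy` nudges and angle sweeps
behave intuitively in previews.

The five styles share two proportion constants, exposed as optional
overrides of `symbol_spec()` so the look can be matched to other tools by
eye:

* head apex **half-angle 30°** — head base half-width is
  `head_length · tan 30°`;
* **barb depth `head_length/3`** — for `POINTY`, how far the back of the
  head is pulled toward the tip.

`DELTA` is a filled (or outlined) isosceles triangle; `POINTY` the same
triangle with the concave barbed back; `CIRCLE` a circle of radius
`head_length` centered on the anchor (the one style that marks rather than
points, so `length` and the shaft are ignored). `THICK` and `THIN` are
both open chevrons and are distinguished as follows: `THICK` is a solid
chevron *band* whose band width equals `thickness`, with its tip vertex on
the anchor; `THIN` is two stroked line segments of stroke width
`thickness`. For every style except `CIRCLE`, a shaft is added only when
`length > head_length`; smaller lengths collapse the symbol to a bare
arrowhead, which is a legitimate annotation in its own right.

Parameters and defaults: `head_length` 10 px, `length` 30 px, `thickness`
3 px, `filled = TRUE`, color `"red"` from a fixed ten-color palette of
exact RGB bytes, `angle` 0°, `dx = dy = 0`. The defaults draw a clearly
visible mid-sized arrow on typical 100–1000 px frames.

## Rasterization: exact pixel rules

Determinism is a contract here: the same overlay on the same movie must
produce byte-identical pixels on any platform, so rendering is integer and
antialiasing-free.

* Continuous coordinates are 0-based, x rightward, y downward, origin at
  the top-left pixel's corner; the pixel stored at `[row r, col c]` has
  its center at `(c − 0.5, r − 0.5)`.
* A pixel belongs to a filled primitive iff its **center** is inside
  (even–odd scanline rule, with the half-open edge convention so vertices
  on a scanline are counted exactly once — the tie-break that keeps
  abutting polygons from double-painting).
* Strokes paint pixels whose centers lie within `thickness/2` of the
  path; circles analogously within `thickness/2` of the circle.
* Items paint in insertion order (painter's algorithm; later wins), and
  everything is clipped to the frame.

A consequence used in the tests: an axis-aligned w × h rectangle on
integer coordinates changes exactly w·h pixels.

Click markers (yellow, `(255,255,0)`) and trajectory markers (brown,
`(165,42,42)`) are fixed 4-px-radius, 1-px-stroke circles. They are
working aids for preview, so `flatten()` excludes them by default
(`include_markers = TRUE` opts in); finished movies show only the symbols.

## Movie I/O

Movies are 8-bit RGB, time-only stacks. A folder of single-frame TIFFs is
ordered by natural numeric sort of the digit runs in the file names
(`t2 < t10`, zero-padding irrelevant), falling back to lexicographic for
ties. Grayscale is promoted to RGB by channel replication; multi-channel
or deeper-than-8-bit data is rejected with instructions to convert to an
RGB stack first, because silently collapsing channels would be lossy in a
way the user should control. TIFF output is uncompressed and round-trips
bit-exactly. AVI output is an uncompressed 24-bit RIFF container written
directly by the package; only frame count and duration are contractual for
AVI (codecs vary across players), so TIFF is the fidelity path.

## The trajectory text format

One record per line, `x, y, frame,` — comma + space separated, trailing
comma, frames 1-based, blank lines ignored, integer and decimal
coordinates both accepted on read. Coordinates are written as the
shortest decimal that parses back to the stored double (integers get a
trailing `.0`), so save→load is exact; `strict_integer = TRUE` rounds to
whole pixels for byte-parity with producers that write integers. A loaded
file *replaces* prior points rather than merging — that is what makes
"load the same file onto another channel's movie" a safe, stateless
operation. Duplicate frame numbers in a file are an error: a file is a
trajectory, not a click set, and silently fusing duplicates would hide a
corrupted file. Out-of-bounds coordinates are allowed at trajectory level
and clipped only at render time, since a symbol may intentionally hang
over the frame edge.

## What the synthetic fixtures emulate

`generate_movie()` renders a bright disc following a
piecewise-constant-velocity path over a Gaussian-noise background —
exactly the motion class the interpolation model assumes — and returns the
ground-truth trajectory alongside. `generate_clicks()` emulates the
labeling behavior: per-axis Gaussian jitter around the truth, plus, at a
configurable rate, a miss-click placed at least `miss_distance` (default
50 px, i.e. ten default spot radii) from the truth followed by corrective
clicks at the true position. All randomness flows from one explicit seed
through a scoped RNG, leaving no global state behind.

What the fixtures deliberately do **not** model: point-spread functions,
photobleaching, drift, occlusion, or curved/zigzag motion. Passing tests
therefore demonstrate that the pipeline is exact under its own motion
model and robust to outlier clicks — not that linear interpolation suits
arbitrarily complex biological motion, which remains the user's modeling
judgment when choosing keyframes.

Problem sizes in the test suite were chosen to exercise the contracts
while staying desk-scale: 500-case property sweeps for text round-trips
and interpolation, 1000 randomized miss-click trials, 100 random rigid
placements at 1e-9 px tolerance, 50 randomized overlays for determinism
and locality, 20 TIFF round-trip movies, and end-to-end fixtures of ~30
frames at ~100×100 px.

## Degenerate inputs and edge rules

* Empty click set or empty trajectory: interpolation and saving error out
  rather than guessing.
* A single keyframe interpolates to itself (stationary annotation).
* `frame_median` of one point is that point.
* Drawing twice without `remove_symbols()` stacks symbols — matching the
  remove-then-redraw workflow, where redraw after removal reproduces a
  single draw item for item.
* `flatten()` returns an emptied overlay, so flattening twice is the
  identity on the second pass; multi-pass annotation (draw A, flatten,
  draw B, flatten) equals painting both item sets in order.

## Known limitations

* No automated tracking, smoothing or splines — by design.
* AVI is written uncompressed; files are large and pixel equality across
  third-party decoders is not promised.
* No z-stacks or OME metadata: time-only RGB stacks.
* Rendering is deliberately aliased; there is no antialiased compositing
  contract.
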