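---
title: "Vessel segmentation and morphometry in IHC images: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vessel segmentation and morphometry in IHC images: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

In brightfield immunohistochemistry (IHC) against endothelial markers
(D2-40 for lymphatic, CD34 for blood vessels), the DAB chromogen renders
vessel endothelium brown on a pale counterstained background, and vascular
lumens appear as bright, nearly unstained regions. Microvessel density and
per-vessel shape (size, roundness, contour regularity) are classic
angiogenesis readouts, but automatic measurement is complicated by vessels
whose stained perimeter is interrupted: an *open* vessel has no closed
contour to measure until the gap is bridged.

`angiopath` implements a two-stage segmenter for tissue-microarray (TMA)
core images:

* **Stage (a), colour:** closed vessels are segmented from the brown stain
  alone, in HSV space.
* **Stage (b), radial:** open vessels are recovered from their lumens —
  a bright region qualifies as a vessel lumen when probes cast outward
  along its boundary normals find membrane staining on a sufficient
  fraction of the boundary. Valid lumens are emitted as closed contours.

Each vessel then receives the morphometric record (position, area, size,
aspect, roundness, perimeter ratio, inner/outer contours) and every image a
vascular-density summary.

## Stage (a): HSV colour segmentation

The RGB image is converted to HSV in the 8-bit convention — H in
[0, 179] half-degrees, S and V in [0, 255]. The published thresholds (30
for S, 20 for H) only make sense under this convention, which is also the
dominant one in imaging libraries; it is fixed here and recorded in the
run metadata. The brown mask is

```
NOT( OR( threshold(S, 30, inverted), threshold(H, 20) ) )
```

i.e. a pixel is brown-stained iff it is saturated (S > 30) **and**
low-hue (H ≤ 20). Low-saturation background (pale tissue, lumens, white
glass) fails the first condition; haematoxylin-blue nuclei fail the
second. All thresholds compare strictly (`pixel > t`).

The mask is cleaned by erosion (2 iterations) then dilation (4
iterations) with a 3×3 square structuring element: erosion removes
speckle, the extra net dilation rejoins endothelial fragments. Pixels
outside the image count as background, so erosion strips the image
border. Contours are traced by Moore border-following with full hole
hierarchy: 8-connected foreground components yield outer contours,
enclosed 4-connected background components yield hole contours (the
standard connectivity duality that keeps boundary topology consistent).
Outer contours are oriented counter-clockwise in the Cartesian (y-up)
frame, holes clockwise, so orientation encodes the contour class. Each
outer contour is paired with its largest hole as the lumen.

Finally the macrophage filter: small brown blobs (immune cells) mimic tiny
vessels. A contour is kept iff it has **more than 6 boundary points and**
a bounding box strictly wider and taller than 20 px. The published step
reads as an "or" between the two conditions, but under "or" every blob
with more than 6 boundary points survives — which defeats the step's
stated purpose of discarding macrophages. The conjunction is therefore the
default; `filter_combinator = "or"` restores the literal reading.

## Stage (b): radial lumen probing

1. The green channel alone separates lumens well (bright, unstained) and
   halves the memory traffic; it is thresholded strictly at 236.
2. Erosion (3) and dilation (2) remove bright speckle; enclosed holes
   smaller than 400 px (strictly) are filled; a second 1-iteration
   erosion widens the moat between lumen boundary and membrane. The
   traced candidate boundary therefore sits a net 3 − 2 + 1 = 2 px inside
   the true lumen boundary.
3. For each boundary point, the tangent is a cyclic central difference
   over a half-window of k = 2 contour points (narrower windows are too
   noisy on digital curves); the outward normal is the tangent rotated
   90°, the side chosen from the polygon winding. Probes sample integer
   offsets 2..30 px along the normal — about 0.5–7.5 µm at 0.25 µm/px, a
   plausible endothelium offset; the range is configurable. A point
   *hits* when any sample lands on the brown mask; samples outside the
   image miss. Probing uses the **raw** (pre-cleanup) brown mask: cleanup
   dilation may bridge exactly the gaps this stage needs to see.
4. A lumen is a valid vessel when its hit ratio reaches a size-adjusted
   threshold: 0.60 for boundaries of ≥ 100 points, 0.80 below that.
   Small lumens are much more artefact-prone (dust, tears, vessel-free
   bright patches), so they must be almost fully enclosed. The two-level
   step function is the simplest monotone implementation of a
   size-dependent ratio; both levels and the knee are configurable and
   recorded in the output metadata.
5. Valid lumens are dilated back by the net 2 px of erosion (so the
   emitted contour sits on the true lumen boundary), re-traced, and
   emitted as closed vessels with the original lumen as inner contour.
   The stage-(a) size filter is applied last.

## Merging the stages

Both stages see every vessel with a closed, stained ring: stage (a) finds
the ring, stage (b) its lumen. The radial detection is then *nested
inside* the colour detection, and nested bounding boxes have low IoU
(roughly the squared ratio of lumen to outer diameter) but near-total
containment. Duplicate suppression therefore uses intersection over the
*smaller* box (> 0.5 ⇒ duplicate, keep the colour detection, whose closed
stained ring is the stronger evidence). Since intersection-over-min is
never below IoU, no two emitted vessels can overlap with bounding-box
IoU above 0.5.

## Morphometry

For a closed contour with vertices $p_i$:

* **area** — shoelace polygon area, in px² and µm² (µm² = px² × mpp²,
  default mpp 0.25 µm/px, always user-overridable; pixel values are
  always emitted alongside so calibration errors are recoverable);
* **size** — tight bounding-box width/height, µm;
* **aspect** — max(w, h)/min(w, h) ≥ 1;
* **roundness** — 4πA/P², 1 for a disc;
* **perimeter ratio** — convex-hull perimeter / contour perimeter, 1 for
  convex outlines, decreasing as boundary indentations deepen (a contour
  regularity measure).

These are computed for the outer and, when present, the inner (lumen)
contour.

**Digitisation correction.** An 8-connected pixel chain systematically
overestimates the length of a smooth curve by ~5% (the classic staircase
bias), which alone drags the roundness of a perfect digital disc to
~0.89. Shape measurement therefore first simplifies the contour by
Ramer–Douglas–Peucker with a 0.8 px tolerance: exact on true polygons (a
digital square keeps its 4 corners, its exact perimeter and area), and on
digital circles it recovers roundness 0.99 and area within 1% of πr².
`simplify_tol = 0` measures the raw chain. Detection geometry (probing,
rasterisation, deduplication) always uses raw chains.

**Vascular density** is reported two ways, since the classic table row
has no fixed definition: vessel count per mm² (classic microvessel
density) and vessel area fraction.

## Synthetic scenes and what they show

No annotated TMA data ships with the package, so evaluation uses a
synthetic generator with object-level ground truth. A scene is a pale
pink background (RGB 232/213/218 — low saturation, pink hue, so it fails
both brown conditions) carrying:

* **closed vessels** — brown annuli (RGB 150/90/40 → H 14, S 187) of
  outer radius 16–36 px and ring thickness 6–10 px with near-white lumens
  (252/252/252, green > 236);
* **open vessels** — the same with an arc of 5–30% of the circumference
  erased to background;
* **distractors** — solid brown discs of diameter 6–15 px, the
  macrophage surrogate and the negative class for specificity (pixel-level
  true negatives are meaningless for object detection);
* Gaussian pixel noise, σ = 2 grey levels.

Radii, thicknesses and noise were chosen once to emulate capillaries to
small venules at 40× (4–18 µm at 0.25 µm/px) while satisfying both
stages' published thresholds by construction; the palette is
configuration, not constant. Objects are placed by rejection sampling
without overlap, fully inside the image; generation is bit-reproducible
per seed.

Detections are scored by greedy nearest-centroid matching within each
truth object's outer radius (IoU matching adds nothing for annular
objects), pooled over scenes. The shipped evaluation uses 20 scenes of
1024×1024 px with 10–50 vessels (closed/open split at random) and 10–30
distractors each — roughly the low-to-middle of the 2–600 vessels per
image that real TMA cores span; this size keeps the whole evaluation in
about a minute while pooling ~500 vessels and ~400 distractors.

What passing shows — and what it does not: the synthetic scenes have
clean annular geometry, a single stain spectrum and no stromal texture,
folds, necrosis or out-of-focus blur. Results on them validate the
*algorithmic contract* (thresholds, morphology, probing, scoring), not
clinical performance on real slides; stain variability in particular is
explicitly out of scope (no colour normalisation is attempted).

## Numerical conventions and degenerate inputs

* Coordinates are 0-based, (x = column, y = row), origin top-left.
* Binary masks are {0, 255}; all threshold comparisons strict.
* Morphology: 3×3 square element; outside pixels are background.
* Hole filling: strictly-smaller-than bound; border-touching background
  is never a hole. The operation is idempotent and never removes
  foreground.
* Empty masks trace to an empty contour list (not an error); contours
  with fewer than 3 points cannot be measured (error).
* A degenerate tangent (coincident points) during normal estimation
  widens the window until it resolves.
* 16-bit TIFF input is rejected by default and linearly rescaled under an
  explicit flag; the pipeline is 8-bit throughout.
* Greedy matching orders candidate pairs by distance with deterministic
  tie-breaks, so scoring does not depend on detection order.
* All randomness lives in the scene generator and is seed-scoped (the
  caller's RNG state is saved and restored).

## Known limitations

* The measurement table is CSV only; there is no XLSX writer dependency
  in this build (`xlsx = TRUE` errors rather than silently omitting).
* Whole-slide pyramidal input, colour deconvolution and stain
  normalisation are out of scope; images are processed whole.
* The radial stage requires a visible bright lumen; vessels with neither
  a closed ring nor a lumen are not detectable by either stage.
* The Canny edge mode for contour extraction is a minimal
  Sobel-plus-hysteresis implementation (aperture 3, defaults 50/150),
  provided for completeness; the threshold path is the default and the
  tested one.
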