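---
title: "Methods: surface recovery, curvature analysis and harvest metrology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surface recovery, curvature analysis and harvest metrology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldvision)
```

This vignette records the models behind each pipeline, the assumptions
they lean on, the defaults and why they were chosen, and what the
synthetic-scene tests do and do not demonstrate about field data.

## Photometric stereo

### Model and assumptions

A fixed camera captures one image per light. Under the Lambertian
reflectance model the radiance at a pixel with surface gradients
$(p, q)$ ($p = -\partial f/\partial x$, $q = -\partial f/\partial y$
for surface $z = f(x,y)$, depth toward the camera) and albedo $\varrho$,
lit from gradient-space direction $(p_s, q_s)$, is

$$R(p,q) = \varrho\,\frac{1 + p\,p_s + q\,q_s}
  {\sqrt{1+p^2+q^2}\,\sqrt{1+p_s^2+q_s^2}}
  \;=\; \varrho\,(\hat n \cdot \hat L),$$

clamped at zero where the surface faces away from the light (attached
shadow). Three assumptions underpin the solve: (1) the object is small
relative to the viewing distance, so lighting is directional and the
projection orthographic; (2) the surface is Lambertian; (3) pixels used
in the solve are free of cast and self shadows. Assumption 3 cannot be
guaranteed in the field, so it is *enforced where checkable*: a pixel
participates only if its intensity lies strictly inside
`(low, high)` = (0.02, 0.98) in every image — the lower bound rejects
shadowed pixels, the upper saturated ones. Both are configurable; the
defaults correspond to the darkest/brightest ~2% of an 8-bit sensor's
range, where clipping and noise dominate.

With exactly three lights the per-pixel system $I = M(\varrho n)$ is
solved by inversion; with more lights by least squares over the
non-shadowed images, which demonstrably reduces noise sensitivity (the
test suite checks the four-light solve beats every three-light subset
under $\sigma = 0.01$ intensity noise). The light matrix must have rank
3 — equivalently the light azimuths must not be collinear — and the
solvers reject configurations that violate this, naming the azimuths.

### Two-source moving-platform variant

A multi-exposure solve fails on a moving rig. With two lights placed
symmetrically on the camera's x axis (the travel direction), at
$(p_s, 0)$ and $(-p_s, 0)$, the Lambertian model gives

$$\frac{I_1 - I_2}{I_1 + I_2}
  = \frac{(1 + p\,p_s) - (1 - p\,p_s)}{(1 + p\,p_s) + (1 - p\,p_s)}
  = p\,p_s,$$

since the slope normalisers and the albedo cancel in the ratio. Hence
`p = ((I1-I2)/(I1+I2))/ps` exactly, independent of $q$ and $\varrho$ —
the derivation behind `two_source_gradient()`. The cost is that only
the x-gradient is observable (2.5D); the test suite verifies both the
$q$-independence and the agreement with the full solve's p-field.

### Gradient integration

PS gradient fields are never exactly integrable (noise, shadows, model
error), so depth is recovered as the least-squares integral: the mean
gradient is integrated exactly as a plane ramp, and the residual by
Frankot–Chellappa spectral projection on an even/odd mirror-extended
domain. The mirror extension (equivalent to a cosine-basis Poisson
solve) exists because a plain periodic solve introduces wrap-around
ringing on non-periodic surfaces; with it, a constant-gradient plane
integrates to machine precision and a sphere cap to ~0.1% RMS of the
cap height. Integrated depth is defined only up to a constant; the
output is mean-centred. Invalid pixels contribute zero residual
gradient, i.e. they are interpolated harmonically.

## Curvature analysis and meristem localisation

Depth maps are treated as Monge patches and differentiated by
Gaussian-smoothed central differences (`sigma` in pixels; 0 disables
smoothing — used in the analytic-surface tests; 1 is the default for
rendered or measured surfaces). The full first-derivative forms are
used for $H$ and $K$ rather than the small-slope approximation because
leaf slopes routinely exceed 0.5. Principal curvatures are
$k_{1,2} = H \pm \sqrt{\max(H^2 - K, 0)}$ (the radicand is clamped:
numerically $K$ can exceed $H^2$ by rounding), and the shape index
$S = (2/\pi)\arctan((k_2+k_1)/(k_2-k_1))$ is undefined at umbilic flat
points ($k_1 = k_2$), where it is returned as `NA`. $S$ is exactly
scale-free for small slopes; under depth scaling with appreciable
slopes it drifts by $O(\mathrm{slope}^2)$, which the test suite bounds
in the shallow regime.

HK segmentation uses the standard eight-class sign table with zero
bands `eps_H` (1/px) and `eps_K` (1/px²). Defaults 0.002 and 1e-5 were
chosen so a surface undulation must exceed a radius of curvature of
~500 px to leave `flat` — appropriate for the rendered scenes here but
deliberately configurable, since the right bands scale with pixel pitch
and noise. The combination $|H| \le \epsilon_H$, $K > \epsilon_K$ is
geometrically impossible when $\epsilon_K \ge \epsilon_H^2$ (as
$K \le H^2$) and is mapped to `flat` for other threshold choices.
The sign convention (depth toward the camera) makes a dome facing the
viewer a `peak` ($H < 0$, $K > 0$) and a depression a `pit`.

Meristem localisation takes the connected components of `pit` pixels
(polarity configurable — some habits present the growing point as a
protrusion), keeps those of at least `min_blob_px` pixels, and reports
each component's $|K|$-weighted centroid scored by mean $|K|$. On the
synthetic rosettes the depression's curvature dominates the inter-leaf
troughs by more than an order of magnitude, so the top candidate is the
meristem; on scenes with multiple rosettes, raising `eps_K` above the
trough curvature (5e-3 in the tests) isolates exactly one candidate per
plant.

The sliding-window gradient-histogram classifier mirrors the
moving-platform case where only the x-gradient exists. Windows are
summarised by L1-normalised histograms of $p$ over fixed symmetric bin
edges; any scalar scorer can be plugged in, and the shipped reference
trainer is a ridge-regularised linear discriminant. Two protocol
details matter and are fixed in the test helper: the background
(negative) pool includes *near-miss* windows from 8 px off-centre
outward — without them the margin cannot reject the dip's shoulder
ring, and localisation degrades from ~9/10 to ~6/10 — and the window
(32 px at stride 2) must cover the whole depression. Ties in the heat
map break by scan order (smallest row, then column).

3D leaf area is $\sum_{\text{mask}} \text{pitch}^2\sqrt{1+p^2+q^2}$ —
the projected pixel area divided by the cosine of the local tilt, which
removes the parallax/foreshortening bias of 2D area estimates. Invalid
pixels inside the mask are excluded and counted in an attribute.

## Weed segmentation by texture entropy

`local_entropy()` computes, per pixel, the Shannon entropy (bits) of
the `n_levels`-bin grey histogram over a centred square window with
reflect padding (for even windows the centre sits left/above the
midline; a 32-px window spans 15 px before and 16 after). The
implementation runs one integral-image box filter per grey level, so
cost is linear in pixels. Defaults: 32-px window (the classic choice
for grass at field scale) and 64 grey levels — enough to saturate the
grass/dock contrast without making windows' histograms sparse.

Segmentation thresholds the entropy map (`dock = entropy < t`), then
opens (disc, 5 px) and closes (disc, 9 px) the mask and removes
components under 200 px — the order matters: opening first removes
speckle the closing would otherwise consolidate. The automatic
threshold is Otsu's method on the entropy map, *accepted only if* the
low class's mean entropy is below 0.75 of the high class's. Dock and
grass entropies differ multiplicatively (a smooth leaf has near-zero
entropy at any illumination, grass several bits), so this ratio guard
is illumination-robust; without it, Otsu on a dock-free scene would
split the unimodal grass distribution and hallucinate weeds covering
half the image. Optional range fusion intersects the mask with a depth
band, reflecting that 3D range thresholding makes 2D weed detection
more reliable.

## Potato metrology

Belt normalisation fits a plane to the deepest 60% of ROI pixels
(tubers are nearer the camera than the belt) by least squares with two
3-MAD trimming passes, and reports heights above it, clamped at zero.
Detection thresholds heights at 8 mm with a 150-px minimum area — both
uncalibrated to any particular rig and therefore exposed as parameters.

Ellipsoid fitting is two-stage. The algebraic stage is the
ellipsoid-specific constrained quadric fit (constraint $4J - I^2 > 0$
as a generalized eigenproblem on centred, isotropically scaled
coordinates): with only the top half of each tuber visible, an
unconstrained quadric fit frequently returns hyperboloids, which this
constraint excludes by construction. With exact data the discriminating
eigenvalue degenerates to zero, so near-zero eigenvalues are accepted
and candidates screened for a real ellipsoid. The geometric stage
refines centre, log-axes and orientation by BFGS on gradient-normalised
(Sampson) point-to-surface distances inside a trust region around the
algebraic solution; this removes most of the noise-induced axis
inflation (the c-axis bias drops from ~+12% to ~+2% at 1 mm depth
noise) while the trust region blocks the degenerate flat-ellipsoid
minimum the raw Sampson objective admits.

Touching tubers first appear as one detection region. If the single
ellipsoid's RMS Sampson residual exceeds 3 mm, the region is split at
the watershed of its (lightly smoothed) height map and each part
refitted, recursing at most twice; parts that still fit poorly are
returned flagged rather than dropped. In the contact zone the height
map is the *max* of the two surfaces, which lies above either one, so
pixels within 5 px of the watershed boundary are excluded from each
part's fit (they remain in the record's pixel support). This exclusion
is what brings touching-pair sizing from ~60% to >99% within 10% on the
synthetic conveyor.

The sieve size of an ellipse with diameters (width, height) — only the
two smaller tuber axes matter for grading, as the major axis never
constrains passage through a square grid — is the minimum over aperture
rotation $\theta$ of the larger axis-aligned extent of the rotated
ellipse, found by 1-D minimisation. (The minimax sits at
$\theta = \pi/4$, giving the closed form
$\sqrt{(w^2+h^2)/2}$; the optimisation route is kept because it
generalises to non-elliptical cross-sections, and the test suite checks
it against an independent boundary-sampling oracle.) Size bands are
half-open intervals $[lo, hi)$ on the configurable edge set
(45, 65, 80) mm; a tuber exactly on an edge grades upward. The band
count is not hard-coded: five-band gradings are a different edge set.

The accuracy metric for caliper-vs-vision comparisons is
$100\,(1 - |T - E|/E)$ — the error taken relative to the *estimate*.
This form reproduces every percentage cell of the reference harvester
trial table shipped in `inst/extdata/` to the printed decimal, which is
how it was identified; it is asymmetric and can go negative for gross
errors, both verified in tests.

## Geo-tagging and yield maps

Records are tagged by linear interpolation between the bracketing GPS
fixes — harvester speed is low and fixes are at 1 Hz, so smoothing
would add nothing — with a ±5 s alignment window outside which records
are dropped and counted. Projection is local equirectangular about the
record centroid: fields are far below the ~1 km scale where its
distortion matters. The grid covers the tagged records' bounding box
padded by one cell (default 5 m); counts are exact integers and every
stage preserves `records = tagged + dropped` and
`sum(grid) = tagged`. Heat maps colour each band on a blue–green–red
ramp scaled per band (matching the practice of publishing one
separately-scaled map per size band; a global-scale flag is provided),
with zero cells transparent, and a GeoJSON of cell polygons carries the
counts for GIS overlay.

## Synthetic scenes: what they emulate, and what they do not

The generators are pure functions of their seed and write the same file
formats the pipelines read (16-bit PNG stacks + YAML light configs,
float-TIFF/TSV depth frames + JSON sidecars, CSV tracks and records).

* **Surfaces** carry exact analytic gradients; the rosette's radial
  sinusoidal leaves are gated off near the centre (a squared radial
  gate) both because an n-fold angular modulation aliases across pixels
  at small radii and because live rosettes are smooth at the whorl; the
  central depression's depth is set so its curvature dominates the
  inter-leaf troughs, as a real meristem depression does. Default
  conditions: 96-px rosettes, mound height 9–14 px, 5–8 leaves, dip
  sigma 2.5–4 px, centre jitter ±12% of the frame.
* **Renders** use the same Lambertian forward model the solver inverts,
  plus additive Gaussian intensity noise and clamping. They include
  attached shadows but *not* cast shadows, inter-reflections or
  specularities — so PS round-trip tests validate the solver's algebra
  and shadow masking, not robustness to non-Lambertian leaves.
* **Conveyor frames** (256 x 352 px at 1.5 mm/px, belt at 800 mm)
  carry true ellipsoids with semi-axes a ∈ 35–60, b ∈ 25–45,
  c ∈ 16–30 mm, 1 mm Gaussian depth noise, optional 1 mm quantisation
  and 20% touching pairs. Real tubers are not true ellipsoids — the
  field experience is that the major axis is over-estimated on real
  potatoes, one reason grading uses only width and height — so the
  synthetic within-10% rates bound sensor-noise behaviour, not shape
  mismatch.
* **Grass/dock textures** are procedural (rank-normalised oriented
  noise vs smooth lobed blobs). That suffices because the pipeline's
  discriminator is entropy, not appearance; it deliberately does not
  probe illumination changes, dried grass, or dock-like smooth objects.
* **GPS scenes** are noise-free serpentine tracks with Poisson-timed
  records; they exercise conservation and geometry, not GPS error.

Problem sizes in the tests and acceptance script (10 seeded renders at
64 px, 20 grass scenes at 256 px, 20 conveyor frames, 20 x 20 sieve
grid) were chosen as the smallest at which the checked statistics are
stable across seeds.

## Numerical choices and degenerate inputs

* Pixels with fewer than three unshadowed intensities are invalid, not
  errors; all-invalid gradient fields refuse to integrate.
* The two-source ratio floors `i1 + i2` at 1e-3 to avoid dividing by
  sensor noise in mutual shadow.
* Entropy bins are `[0,1]` quantised at `n_levels`; strictly monotone
  grey remappings that preserve bin assignment leave the map bit-identical.
* Ellipsoid fits require ≥30 non-coplanar points; coplanar debris is
  flagged low-confidence by the splitting pipeline, and failed fits
  fall back to bounding-box sizing in `measure_tubers()`.
* Duplicate GPS timestamps collapse to the last fix; records inside the
  window but beyond the track ends take the nearest end fix.
* Depth rasters are stored as float32 TIFF scaled into [0, 1] with the
  scale in the JSON sidecar (lossless to float32 precision); `.tsv`
  text frames are exact. 16-bit PNG output uses the package's own
  minimal encoder.

## Known limitations

Uncalibrated PS (unknown light directions), non-Lambertian reflectance
models and specularity removal are out of scope, as are learned weed
classifiers (the scorer contract is the extension point), live device
I/O, and satellite-imagery overlay for the yield maps. The HK
thresholds and detection defaults are calibrated to the synthetic
conditions above, not to any particular camera rig; a deployment should
re-derive them from its pixel pitch and noise floor.
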