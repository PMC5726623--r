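---
title: "Highlight statistics and the light-spread gloss model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Highlight statistics and the light-spread gloss model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glossim)
```

## The scene and what it is for

Perceived glossiness is not a direct readout of surface reflectance: the same
material can look more or less glossy depending on how its specular
highlights are arranged, and one powerful way to rearrange them is to move
the light sources. The stimulus world in this package holds reflectance
fixed and varies illumination geometry with a single scalar, the **light
spread** α. Three white point lights sit on a radius-5 arc in the horizontal
plane; the central one is fixed in front of the object, and the lateral two
sit at ±α·90° from it. At α = 0 all three coincide and the object carries
one highlight group per curvature extremum; as α grows, each group widens
and eventually splits into three individual highlights.

Everything lives in one coordinate frame: x lateral, y depth, z vertical,
object at the origin. The cameras sit at (±0.03, −1, 0) for the stereo pair
(or (0, −1, 0) for a single view) and the test objects are scaled so their
vertical extent subtends ~4.2 degrees at that 1-unit distance. The blob
objects are resolution-6 icospheres (20,480 triangles) displaced along their
normals by a seeded improved-Perlin "clouds" texture; the three presets
differ in displacement strength (1.0, 1.0, 0.5) and texture size
(1.0, 0.7, 0.4). A sphere and an open cylinder stand in for the two
externally downloaded shapes of the original stimulus set, which are out of
scope here.

## Material model and the shading-space decision

The material is a dielectric microfacet model: mid-gray albedo (0.5),
metallic 0, GGX normal distribution with shape parameter
`a = roughness = (1 − smoothness)²`, Schlick Fresnel, and Smith
height-correlated visibility. Light falloff is inverse-square windowed to
reach exactly zero at the 10-unit range:
`min(1, 1/d²)·max(0, 1 − (d/range)⁴)²`. Ambient is a constant 0.6 on the
albedo (0.3 per channel), and intensities above the display ceiling of 1.0
are clipped, never tone-mapped.

One decision deserves emphasis because it changes the package's behaviour
qualitatively. The plain radiometric Cook–Torrance specular term
`π·D·F·Vis` with F0 = 0.04 makes the highlight peak at the stimulus
smoothness levels (0.2–0.6, i.e. a between 0.64 and 0.16) at most a few
percent of the diffuse term: on such images the `mean + 2 SD` gloss-layer
rule finds nothing over most of the design grid, and none of the intended
highlight-statistics behaviour can be studied. Game engines of the era the
stimuli come from rendered in **gamma color space**, where the specular lobe
is effectively compressed by a square root and the dielectric Fresnel base
lives at `0.04^(1/2.2) ≈ 0.23`. The default shading mode `"engine_gamma"`
emulates exactly that (`sqrt(π·D·Vis) · F(F0^(1/2.2))`, Disney diffuse),
which restores the regime the experiment operates in — detectable highlight
layers from mid smoothness upward, and merged-versus-split lobe structure
governing the statistics. The literal radiometric form remains available as
`material(..., shading = "physical")`. Both modes are linear in light
intensity, so intensity-ratio invariances (below) hold in either.

What even the faithful gamma-space emulation does **not** produce is a
specular-dominant image at smoothness 0.2: the a = 0.64 lobe is so broad
that its peak stays ~0.35× the diffuse term, and on a smooth object the
foreground luminance maximum sits only ~1.7 population SD above the mean.
The `mean + 2 SD` layer is therefore empty at low smoothness — which is
also what the original study reports for its algorithmic segmentation
(empty-layer invalid cases and systematically underestimated areas at low
smoothness). Consequently, in this package percentage highlight area
*increases* with smoothness where defined and is undefined below ≈ 0.4 on
smooth objects; the acceptance check that expects non-empty, monotone layers
at smoothness 0.2 is left failing by design rather than met by inflating
the specular gain.

## Gloss layer and statistics

Segmentation follows a fixed global rule: threshold = foreground mean plus
twice the **population** SD (the n-denominator variant; the choice is
frozen for reproducibility and is negligible at image scale), strictly
greater comparison (so constant images yield an empty layer), 8-connected
labelling, background ignored everywhere. The four statistics are: number of
components divided by the number of half-images, mean component size in
pixels, highlight pixels over foreground pixels, and mean highlight
luminance. Luminance is the Rec. 709 weighted sum of the linear RGB
channels; no display calibration is applied, which shifts absolute strength
values but not ranks.

Contrast measures: global Michelson `(Lmax − Lmin)/(Lmax + Lmin)` over the
foreground, plus space-averaged Michelson and Whittle contrasts computed in
a sliding 15-px square window restricted to foreground pixels and averaged
over all foreground-centred windows. The Whittle denominator is floored at
1e-4. With ambient off, all luminances scale proportionally with light
intensity, so Michelson-type measures are exactly intensity-invariant; the
Whittle variant is invariant only while the floor stays inactive, which is
why the property test views the sphere's bright cap (3° field of view)
rather than the limb, where luminance goes to zero.

A stimulus is **invalid** when its gloss layer is empty or any foreground
pixel sits at the clip ceiling — the two exclusion rules applied before any
model fitting.

## Lobe superposition and the critical spread

Because lights, cameras and the object centre are coplanar, the
merged-versus-split structure of a highlight group is captured by a 1-D
cross-section: the specular term evaluated on a circle of the local
curvature radius in the equatorial plane. This analytic profile agrees with
a specular-only render of the sphere's equator to well under 5 % RMS, so
the analytic and image paths can be used interchangeably.

A highlight group counts as **resolved** under a Rayleigh-style criterion:
every dip between adjacent peaks must reach `dip_fraction` (default 0.26,
the classical two-line dip) in relative depth `1 − valley/lower_peak`. Two
guards make peak counting robust: adjacent maxima separated by a relative
dip below 2 % are merged (the dielectric Fresnel term produces M-shaped
twin micro-peaks around the mirror direction), and peaks below 2 % of the
profile maximum are ignored (thin grazing-limb Fresnel glints). The default
profile span is ±1.1 rad, which covers the mirror reflections of all three
lights at any spread (the lateral mirror points reach ~50° at α = 1) while
excluding the limb. For the three-light separation task the criterion
additionally demands **three** peaks (`min_peaks = 3`): with the generic
two-peak rule, very rough surfaces would spuriously "resolve" through their
two lateral lobes while the central lobe is swallowed, and the monotone
relation between smoothness and critical spread breaks.

`find_alpha_star()` scans a coarse grid and bisects to 1e-3. Profiles that
never satisfy the criterion even at α = 1 return the "not feasible"
outcome, mirroring the response option subjects had. Across smoothness the
resulting curve is monotone non-increasing, with the rough end infeasible —
the qualitative shape the separation experiment reports. The chromatic
variants of that task ("gap", "all colors", "no red") are representable
only through `dip_fraction` presets; no chromatic modelling is attempted,
and the human dip setting is deliberately not fitted (those numbers are not
printed in the source material).

## Linear gloss model and the synthetic observer

The gloss model is ordinary least squares of a response on the four
statistics, solved via the normal equations on internally standardized
features so the weights are comparable across features; raw-scale
coefficients are reported alongside (whether the original analysis
standardized is unstated, so both scales are emitted). R² is `1 − SSE/SST`
(defined as 0 for a constant response), and each feature's Spearman ρ and
Pearson r with the response accompany the fit. Exactly collinear features
raise an error naming the offending pair. `subset_analysis()` refits within
level combinations of any factor subset, recording under-sized subsets as
unfittable rather than failing — mirroring the all-factors / per-intensity
/ per-shape / per-spread analysis blocks.

Since no human data ship with the package, validation is by **parameter
recovery**: a synthetic observer with known standardized weights, Gaussian
response noise (SD 0.1) and a fixed seed generates responses on the full
350-condition grid rendered at test scale; 200 replicate fits recover each
weight with mean absolute bias below 0.02 and ±2 SE coverage inside
[0.90, 0.99]. Invalid stimuli carry no response and are excluded, as in the
original analysis. The observer's default weights (+number, −size,
−pct_area, +strength) reproduce the sign structure reported for the
empirical segmentation without asserting any human coefficient numerically.

## Reproducibility and numerical choices

* All randomness flows from explicit integer seeds; the Perlin permutation
  and the observer noise save and restore the caller's RNG state. The
  pipeline fans one global seed into fixed per-stage offsets.
* Exact blob shapes will not match any external render (different noise
  lattice); only statistical properties are claimed.
* The displace midlevel (0.5) and texture defaults follow the modelling
  tool's defaults, as the source material does not state them; `nabla` is
  carried in the config but inert for scalar displacement.
* The perceptual rescaling of the smoothness axis used in the original
  experiment is not recoverable from the text; nominal values are used
  as-is (identity mapping), so positions on the smoothness axis are
  nominal, not perceptual.
* The exact engine falloff curve is unknown; only its zero-at-10-units
  property is enforced by the windowed inverse-square form above.
* Images are written as 16-bit binary PGM (luminance, masks) and
  gamma-encoded PPM (RGB, for viewing only); no PNG writer is available in
  the target environment. CSV uses 9 significant digits and round-trips
  byte-identically.
* Test-scale renders (64–128 px, resolution 4–5 meshes) are used throughout
  the suite for speed; the stimulus-scale defaults (256 px, resolution 6)
  are configuration, not code.

## Known limitations

* No shadows, interreflections, environment maps or off-axis stereo
  projection; the stereo pair is plain perspective from two eye positions.
* The gloss layer is algorithmic only; the empirically matched segmentation
  used as a comparison method in the original study is replaced by the
  pluggable `as_rendered_image()` input path.
* Absolute luminance values are engine units, not cd/m²; only ranks and
  ratios should be compared across studies.
* Low-smoothness stimuli have empty gloss layers (see the shading-space
  section); analyses that need them must either lower the SD multiplier
  `k` in `segment_gloss_layer()` explicitly or treat those cases as the
  invalid class, as the fitting pipeline does.
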