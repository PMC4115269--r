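---
title: "Hierarchical shape detection with trainable COSFIRE filters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical shape detection with trainable COSFIRE filters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`scosfire` implements a three-layer, trainable shape-detection hierarchy
modeled on the ventral stream of visual cortex (V1/V2 → V4 → TEO/IT):

1. **Gabor energy front end** (V1/V2 analogue).  A bank of quadrature
   Gabor pairs measures oriented contour energy
   $E_{\lambda,\theta}(x, y) \ge 0$ at every pixel.  Energy (the root of
   the summed squares of the even and odd responses) is invariant to
   contrast polarity.
2. **V-COSFIRE vertex detectors** (V4 analogue).  A vertex filter is a
   set of tuples $(\lambda, \theta, \rho, \varphi)$: it expects Gabor
   energy in channel $(\lambda, \theta)$ at polar position
   $(\rho, \varphi)$ relative to its center.  The package ships a bank
   of 60 such filters — 12 arm-bisector orientations (steps of $\pi/6$)
   × 5 apertures ($\pi/6 \dots 5\pi/6$) — each configured automatically
   from a rendered synthetic vertex.
3. **S-COSFIRE shape detectors** (IT analogue).  A shape filter is a set
   of tuples $(V_i, \rho_i, \varphi_i)$ referring to vertex filters at
   polar positions around a point of interest.  It is configured from a
   *single* prototype image and responds, at every pixel, to spatial
   arrangements of vertices similar to the prototype's.

Both COSFIRE levels share one combination rule.  Each subunit response
map is thresholded at a fraction $t_1$ of its global maximum, pooled by
a Gaussian-weighted grayscale dilation

$$s_i(x, y) = \max_{|x'|,|y'| \le 3\sigma_i}
  \left\{\, r_i(x - x' - \Delta x_i,\; y - y' - \Delta y_i)\,
  G_{\sigma_i}(x', y') \right\},
  \qquad \sigma_i = \sigma_0 + \alpha\rho_i,$$

with $\Delta x_i = -\rho_i \cos\varphi_i$,
$\Delta y_i = -\rho_i \sin\varphi_i$, so every subunit's response lands
on the filter center, and combined by a **weighted geometric mean**

$$r(x, y) = \Big(\prod_i s_i(x, y)^{\omega_i}\Big)^{1/\sum_i \omega_i},
  \qquad \omega_i = e^{-\rho_i^2 / 2\sigma'^2},$$

followed by thresholding at a fraction $t_3$ of the output's maximum.
With $\sigma' = \rho_\max / \sqrt{2\ln 2}$ the weights decay from 1 at
the center to exactly 0.5 at the outermost tuple; $\rho_\max = 0$ is
treated as the equal-weight (plain geometric mean) case.  The geometric
mean is an AND gate: a missing part zeroes the response, which is what
separates this model from summation-based part detectors — a scrambled
set of the prototype's parts scores zero, while a heavily eroded but
correctly arranged version still scores high.

Geometric tolerance comes from manipulating tuple sets, not from extra
training examples: rotation by $\psi$ maps
$(\theta, \varphi) \to (\theta + \psi, \varphi + \psi)$, scaling by
$\upsilon$ maps $(\lambda, \rho) \to (\upsilon\lambda, \upsilon\rho)$,
reflection about the y-axis maps
$(\theta, \varphi) \to (\pi - \theta, \pi - \varphi)$; the invariant
response is the pixel-wise maximum over a set of transformed filters,
with the winning transform recorded per detection.

## Automatic configuration

**Vertex level.**  Around the point of interest, Gabor energy is sampled
on concentric circles (radii in steps of 4 px starting at 0).  Angular
positions where the orientation-pooled energy has a strict local maximum
above $t_1$ times the stack-wide maximum become tuples, tagged with the
locally dominant channel orientation.  At radius 0 one tuple is emitted
per orientation channel that is a local maximum *across orientation* —
at a two-arm junction this yields one tuple per arm, which anchors the
filter on the apex rather than letting it slide along a single arm.
The default $t_1 = 0.3$ separates true arm maxima (≈ 0.8–1.0 after
calibration) from the energy overshoot that appears just beyond a line
end (≈ 0.25).

**Shape level.**  Every bank filter is applied to the prototype; the
per-pixel maximum across the bank is reduced to its strict 8-neighbor
local maxima (plateau ties keep the lexicographically smallest pixel);
maxima below $t_2$ (default 0.75) times the map's global maximum are
discarded — these are the *dominant* vertices; maxima closer than
`merge_radius` (default 5 px) merge into the strongest, absorbing
rasterization jitter around one physical corner.  Peak positions are
refined to sub-pixel accuracy by a 1-D quadratic fit per axis before the
polar conversion.  At each kept point, *every* bank filter whose
response reaches $t_2$ times the best response *at that point* is
selected (several vertex filters may describe one corner), one tuple per
(filter, point) pair.  The per-location reading of the selection rule
lets weak-contrast vertices contribute; the global cut on the points
themselves is what reproduces the clean three-tuple description of a
triangle — without it, every faint local maximum along a straight edge
would inject tuples.

## Parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| $\lambda$ | Gabor wavelength (px/cycle) | 4 | matched to 3 px strokes |
| bandwidth | Gabor bandwidth (octaves) | 1 | envelope σ ≈ 0.56 λ |
| aspect | envelope aspect ratio | 0.5 | elongated along the line |
| $t_1$ | subunit threshold fraction | 0.3 (config) | 0–0.3 in presets |
| $t_2$ | vertex selection fraction | 0.75 | configuration only |
| $t_3$ | output threshold fraction | preset-dependent | 0.1–0.2 |
| $\sigma_0$ | base blur (px) | 0.1 | positional tolerance at ρ = 0 |
| $\alpha$ | blur growth rate | 0.0853 | tolerance grows with ρ |
| radii | configuration circles (px) | 0, 4, 8, 12 | 4 px steps |

Small $\alpha$ suits rigid shapes; larger values trade selectivity for
generalization (the deformable-object presets use $\alpha$ up to 0.67).
Three parameter bundles are available through `preset()`; see its help
page.

## Numerical choices

* **Channel calibration.**  Each energy channel is divided by the
  maximal response of an ideal straight line (width $3\lambda/4$)
  rendered *at that channel's own orientation*, so a well-matched
  contour scores ≈ 1 in every channel.  Per-orientation calibration —
  rather than one bank-wide constant — also compensates the sampling
  anisotropy of near-Nyquist kernels on the pixel grid (≈ 11% between
  axis-aligned and diagonal orientations at λ = 4), which matters
  because the $t_2$ rule and the geometric mean compare channels
  across orientations.
* **Coordinate frame.**  Internally x grows rightward and y *upward*
  ("math-y-up", tagged in serialized filters), so $\varphi = \pi/2$ is
  north and the shift formulas are literal.  Conversion to raster
  row/col happens only at image I/O; detections report both frames.
* **Dilation window.**  Integer offsets within $\pm\lceil 3\sigma
  \rceil$, Gaussian evaluated at integer offsets and peak-normalized
  ($G(0,0) = 1$) so a subunit response passes through undiminished at
  zero positional error; area normalization would make responses
  σ-dependent.  Shifts are rounded to whole pixels (half-up): the blur
  tolerance $\sigma_0 + \alpha\rho$ dominates the sub-pixel residual,
  and interpolating inside a max operation would blur peak values.
  Near image borders the dilation grid is extended by the shift so the
  pooled window still reaches every in-bounds pixel; the implementation
  is exactly the brute-force per-pixel evaluation (this equality is
  tested on random maps).
* **Thresholds** are fractions of each map's own global maximum,
  recomputed per image; `threshold_fraction()` zeroes sub-threshold
  values and keeps the rest unchanged (soft threshold, idempotent).
* **Degenerate inputs.**  Blank prototypes raise configuration errors;
  all-zero maps pass through thresholding unchanged; $\rho_\max = 0$
  falls back to equal weights.
* **Surround suppression** (off by default, on in the cluttered-scene
  preset) subtracts `coefficient ×` the ring-averaged orientation-pooled
  energy (positive part of a difference-of-Gaussians ring, outer σ four
  times the envelope σ), floored at zero.

## The synthetic stimuli

All test imagery is generated by the fixtures module: white-on-black
anti-aliased contours, default stroke width 3 px (near-optimal for the
λ = 4 channel).  `make_triangle()` renders the equilateral-triangle
prototype (circumradius *R*, apex north by default: corners at polar
angles apex + {0, 2π/3, 4π/3}); `make_kanizsa_triangle()` places three
filled pac-man discs whose wedge cuts (aperture π/3, bisector pointing
at the interior) align with the absent sides — the configured triangle
filter detects this illusory triangle because the wedge tips are
genuine π/3 vertices in the right arrangement; `make_square()` and
`make_fig1_variant()` produce the square prototype and its partial
(25% of contour pixels, corners intact), closed-polygon (shared bottom
half) and scrambled (seeded displacement of half-edge segments)
variants; `make_scene()` composites items with a ground-truth table.

What the stimuli do *not* emulate: photometric noise, texture,
occlusion, perspective, and the stroke-width variability of natural
images.  Green tests on these fixtures demonstrate the combination
machinery, configuration logic and invariance algebra — not robustness
to real-scene nuisances, which in practice is governed by the blur
parameters, surround suppression and the threshold fractions.

## Known limitations

* **Vertex localization bias.**  Corner energy peaks ~1–2 px inside the
  geometric apex (the blur window and arm tuples tolerate small inward
  drift, and arms extend inward), so configured tuple radii
  systematically read ≈ 1.5 px short: the triangle prototype with
  corners 50 px from the center configures at ρ ≈ 48.3–48.5.  This is
  within the vertex detectors' localization tolerance (± 2 px) and is
  self-consistent — the same bias appears at application time, so
  detection positions are unaffected.
* **Bank orientation quantization.**  The 60-filter bank spaces
  arm-bisector orientations by π/6.  Prototypes whose corner bisectors
  fall exactly between grid orientations (an axis-aligned square:
  45° + k·90°) are poorly represented — near-straight contour filters
  can outscore the 15°-misaligned corner filters and configuration
  picks up edge tuples.  Rotating the prototype onto the grid (or
  densifying the bank) restores clean corner tuples; the property tests
  use a square rotated by π/12 for this reason.
* **Problem sizes.**  The worked examples run on 512 × 512 canvases
  with the 60-filter default bank; the bank's synthetic vertices use
  151 px canvases with 60 px arms, and cross-match and equivariance
  properties are exercised on 256 px canvases (circumradius 40).
* The hierarchy is fixed at three layers, and the number and placement
  of subunits is determined by the single prototype; learning them from
  multiple positive/negative examples is out of scope.
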