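---
title: "Entropy-guided joint-vector LBF segmentation of juxta-vascular pulmonary nodules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-guided joint-vector LBF segmentation of juxta-vascular pulmonary nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A juxta-vascular pulmonary nodule is attached to a blood vessel whose CT
gray values are nearly identical to the nodule's. Region-based active
contours driven by CT intensity alone therefore leak along the vessel: the
contour finds no gray edge at the nodule-vessel junction and engulfs the
vessel. On the PET side the picture is different: a metabolically active
nodule takes up far more tracer (a higher standardized uptake value, SUV)
than a small vessel, whose blood-pool signal is further diluted by partial-
volume averaging. `petctseg` combines both channels: a local binary fitting
(LBF) level-set whose data terms jointly fit CT and SUV, weighted by an SUV
information-entropy *edge guide* that freezes the contour wherever local
uptake is homogeneous.

## Pipeline

1. **ROI extraction.** The lung parenchyma is segmented on CT by Otsu
   thresholding (low-gray class), border-touching components are discarded
   (outside air), holes are filled (nodules and vessels sit as high-gray
   islands inside the parenchyma), a morphological opening with a 2 px disk
   cleans the mask, and the largest one or two components remain. The pixel
   with maximal SUV inside the lung mask becomes the template centre `O`,
   and a disk of radius `R = 30` mm (nodules are at most ~30 mm across)
   bounds all later computation.
2. **Initial contour.** Inside the ROI, a gray threshold is found by
   fixed-point iteration on class means: `T0 = (Gmax + Gmin)/2`, split at
   `T`, update `T` to the midpoint of the two class means, stop when the
   change is at most `lambda = 0.1`. The raster is binarized at `T`
   (`>= T` is nodule class) and the boundary of the largest 8-connected
   component (holes filled) is the initial contour. On juxta-vascular
   cases this contour deliberately includes the attached vessel — the
   evolution removes it.
3. **Level-set evolution** (below), initialized as the signed Euclidean
   distance to the initial contour, positive inside.
4. **Evaluation** against ground truth by Dice overlap (percent), symmetric
   Hausdorff distance between 4-neighbour boundary pixel sets (mm), and the
   false-positive fraction relative to the truth area (percent; may exceed
   100 under gross oversegmentation).

## The energy

With `H_eps` the arctan-smoothed Heaviside of width `eps = 1` and `phi`
positive inside, the total energy is

```
F = sum_x [ l1 e1(x) H_eps(phi) + l2 e2(x) (1 - H_eps(phi)) ]
    + nu * sum_x delta_eps(phi) |grad phi|          (contour length)
    + mu * sum_x (|grad phi| - 1)^2 / 2             (distance regularity)
```

The data terms are entropy-weighted joint residuals

```
e1 = F1 [ L1 (I_ct - f1_ct)^2 + L2 (I_suv - f1_suv)^2 ]
e2 = F2 [ L1 (I_ct - f2_ct)^2 + L2 (I_suv - f2_suv)^2 ]
```

where `f1`/`f2` are the classic LBF inside/outside fits — Gaussian-kernel
local averages gated by `H_eps(phi)` — computed per channel with kernel
standard deviation `sigma = 1.5` px. SUV is min-max rescaled to `[0, 255]`
over the ROI so the channel coefficients `L1 = L2 = 1` compare like with
like. Gradient descent gives the update

```
dphi/dt = -delta(phi) (l1 e1 - l2 e2)
          + nu delta(phi) div(grad phi / |grad phi|)
          + mu (lap phi - div(grad phi / |grad phi|))
```

The distance-regularizing term keeps `|grad phi|` near 1 in place of
periodic reinitialization. Evolution stops when the energy is stable
(`|F_k - F_(k-1)| <= chi = 1e-3`) or after `K_max = 300` iterations.

## The edge guide

At a contour point `x`, a disk `R(x)` of radius `r = 15` px is cut by the
zero level set into an inside part (`phi >= 0`, `n3` pixels) and an outside
part (`n4` pixels). Each part's SUV values are summarized by a Gaussian
(mean, standard deviation floored at `sigma_floor = 1e-3` SUV); the
densities at the part's pixels are normalized to a probability vector whose
Shannon entropy `H_i` (bits) is at most `log2(n_i)`, with equality exactly
when the normalized densities are equal — i.e. when the part is
homogeneous. A part that mixes nodule and background uptake asymmetrically
has an entropy *deficit* `D_i = log2(n_i) - H_i > 0`.

The guide weight used in the energy is

```
F_i(x) = 2^-( H_i + log2(m / n_i) )  =  2^(D_i) / m ,   0 < F_i <= 1,
```

with `m = n3 + n4` the grid-clipped disk size. Two deliberate choices:

* **Base-2 exponential.** The entropy is measured in bits, so the matching
  exponential is base 2; `2^-H` is the inverse perplexity of the
  distribution, a unit-free probability-scale quantity. Exponentiating a
  bit-valued entropy with base *e* makes the weight depend on the entropy
  unit, and at `r = 15` (`H ~ 8.5` bits) yields weights around `2e-4` that
  crush the data terms four orders of magnitude below the length term
  `nu = 0.001 * 255^2`: the evolution degenerates to curvature flow and the
  contour shrinks to nothing. We observed exactly this collapse on default
  phantoms.
* **Size standardization.** The raw entropy carries a `log2(n_i)` term that
  says nothing about homogeneity: a half-disk of 350 homogeneous pixels
  scores higher than one of 30. Left in place, the smaller half of every
  neighbourhood is weighted more strongly, which biases the force balance
  toward the smaller region — for a nodule smaller than the disk this is a
  systematic inward force, and once the contour slips inside the nodule the
  outside fit absorbs the abandoned ring and the slip ratchets (we observed
  one-way erosion and eventual annihilation of 3–5 mm nodules). Referring
  both halves to the common size `m` removes the artifact while preserving
  the defining monotone law: the more homogeneous the part, the larger its
  entropy, the smaller its guide weight, and the more firmly the contour is
  frozen there.

The intended dynamics follow directly. Along the vessel, both halves are
SUV-homogeneous (vessel uptake is near background), so `F1, F2 ~ 1/m`, the
CT-driven leak force is suppressed, and the length term retracts the
high-curvature vessel stub from its tips. At the nodule boundary the SUV
edge makes any displaced contour see a mixed half; the deficit raises `F`
there and the large joint residuals push the contour back — the contour
locks onto the SUV edge, which coincides with the true nodule boundary.

The guide is recomputed every iteration, but only where it can act: the
data force carries a factor `delta_eps(phi)`, so the guide is evaluated on
the band `|phi| <= band_px` (plus all zero-crossing pixels) and set to 1
elsewhere. `band_px` defaults to 6, the fitting kernel's 4-sigma support:
beyond it the inside and outside fits coincide and the unweighted data
forces cancel by themselves. Banding on the level value rather than on the
Euclidean distance to the crossing matters: during fast retraction `phi`
can form flat plateaus whose pixels are far from any crossing yet have
small `|phi|` and hence non-negligible Dirac weight; leaving them unguided
injects raw LBF forces that fragment the contour. The per-point
neighbourhood statistics are computed in compiled code; `band_px = Inf`
evaluates the guide at every pixel and is verified in the tests against
the scalar per-point implementation.

## Numerical scheme

* Explicit updates with base step `dt = 0.1`. The effective step is clamped
  so no pixel's level moves more than `max_disp = 1` per update, and it is
  halved — persistently, up to 12 times per run — whenever a step would
  increase the energy under the current (frozen) data terms. A per-step
  reset of `dt` lets later iterations re-probe unstable step sizes; we saw
  it drive oscillatory blow-ups of the distance-regularity term.
* Spatial operators use central differences with replicated borders;
  `|grad phi|` is floored at 1e-10 in the curvature, fit denominators at
  1e-12. The Gaussian kernel is truncated at 4 sigma and renormalized.
* `phi` is initialized as the signed Euclidean distance transform of the
  initial mask (a level-set function must be a regular signed function;
  the distance transform is the standard choice consistent with the
  positive-inside convention and the distance regularizer).
* Ties: `phi = 0` counts as inside; gray exactly at the threshold counts
  as nodule class; equal-area components are resolved by first pixel in
  row-major order; equal maxima of SUV by smallest row then column.
* Degenerate inputs (constant rasters, empty masks, a vanished zero level
  set) raise classed errors rather than returning silent defaults.

## The phantom

The generator renders a 128 x 128 slice pair at 1 mm spacing: a bright
thorax background (gray 200), a circular lung field of dark parenchyma
(gray 40), a vessel segment (width 3 mm, length 30 mm, gray 145) whose
centreline runs through the nodule, and the nodule disk itself (gray 150) —
near-identical to the vessel in CT, which is precisely the juxta-vascular
difficulty. The truth mask is the exact rasterized nodule disk (pixel
centre inside the circle; boundary ties inside), excluding the vessel.

SUV levels are physiological rather than contrast-maximizing: nodule 8
(active lesion), vessel 1.0 (small-vessel blood pool after partial-volume
dilution), parenchyma 0.5. The vessel-to-parenchyma SUV step is deliberately
small — the method's premise is that vessels are *invisible* in SUV relative
to the nodule; a strongly SUV-positive vessel would be segmented as lesion
by any uptake-driven method. The CT channel is multiplied by a low-order
cosine bias field (amplitude 0.1 around 1) to exercise the LBF model's
tolerance of smooth inhomogeneity, and both channels receive additive
Gaussian noise (CT sigma 5 gray levels, SUV sigma 0.15).

Cohorts jitter nodule radius uniformly in 3–12 mm, vessel angle in
0–180 degrees, vessel width by ±30 %, and nodule centre by ±5 px, each
sample under its own derived seed; a cohort is bit-reproducible from the
base spec and one integer seed.

An optional `pet_block_factor` switch (off by default) block-averages the
SUV layout over coarse blocks and bilinearly upsamples it back, emulating
the blur that registering a low-resolution native PET grid onto the CT
grid introduces.

What the phantom does **not** emulate: PET point-spread blur beyond that
resampling, attenuation or reconstruction artifacts, textured parenchyma,
airways, multiple vessels, non-circular nodules (spiculation, cavitation),
and 3D context. Passing the phantom cohort therefore shows that the
algorithm does what its design intends under its stated assumptions — not
that it reaches the same accuracy on clinical images.

## Problem sizes and run times

The test-suite and acceptance cohorts use 20 phantoms on 128 x 128 grids
with the full `K_max = 300` iteration budget; a single segmentation takes a
few seconds on one CPU, a cohort with its classic-LBF baseline a few
minutes. These sizes were chosen so the whole suite exercises every stage,
including both evolutions, at full parameter settings.

## Known limitations

* The stopping tolerance `chi = 1e-3` is absolute while the energy scale is
  ~1e6 on 0–255 intensities, so runs typically use the full iteration
  budget; the result is governed by the stable force balance rather than by
  early termination.
* The classic-LBF baseline shares the numerical stepper with the full
  model; the reduction test (`L2 = 0`, guide off, pixel-identical output)
  checks algebraic consistency of the two data paths, not an independent
  discretization.
* A vessel much wider than the nodule, or a nodule whose uptake is as low
  as blood pool, violates the method's premises and will leak exactly as
  CT-only LBF does.
* Single 2D slices only; the 30 mm ROI assumes one dominant hot nodule in
  the lung field — multiple hot lesions would need per-lesion ROIs.
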