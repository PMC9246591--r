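---
title: "Quadrant-symmetry accelerated fan-beam filtered back-projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quadrant-symmetry accelerated fan-beam filtered back-projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symfbp)
```

## The problem

Filtered back-projection (FBP) reconstructs a 2-D image from projections.
In fan-beam geometry the rays diverge from a point source at distance $D$
from the isocenter; a point at polar coordinates $(r, \varphi)$ seen at
view angle $\beta$ projects to the flat virtual-detector coordinate

$$ s' = \frac{D\, r \cos(\beta - \varphi)}{D + r \sin(\beta - \varphi)},
\qquad
U = \frac{D + r \sin(\beta - \varphi)}{D}, $$

where $U$ is the dimensionless source-to-point distance ratio and the
back-projection accumulates filtered detector samples with weight $1/U^2$.
The back-projection stage dominates the cost: the straightforward
implementation evaluates a sine, a cosine and one $(U, s')$ pair for every
(pixel, view) combination.

This package implements a quadrant-symmetry reorganization of that stage.
A centered square grid is invariant under quarter turns, so its pixels
split into orbits of four points
$E(r, \varphi),\ E_1(r, \varphi+90^\circ),\ E_2(r, \varphi+180^\circ),\
E_3(r, \varphi+270^\circ)$ sharing one radius. Splitting the full turn of
view angles into the four half-open regions $(0^\circ, 90^\circ]$,
$(90^\circ, 180^\circ]$, $(180^\circ, 270^\circ]$, $(270^\circ, 360^\circ]$,
the pair $(U, s')$ is invariant under the simultaneous quarter turn of
point and view,

$$ U(r, \varphi, \beta) = U(r, \varphi + 90^\circ, \beta + 90^\circ), $$

and the pairs of the rotated points at the *same* view follow from the
quarter-turn identities $\sin(\alpha + 90^\circ) = \cos\alpha$,
$\cos(\alpha + 90^\circ) = -\sin\alpha$ (and their $180^\circ$/$270^\circ$
analogues) without any new trigonometric evaluation:

$$ U(r, \varphi + 90^\circ, \beta) = \frac{D - r\cos(\beta-\varphi)}{D},
\qquad
s'(r, \varphi + 90^\circ, \beta) =
  \frac{D\, r\sin(\beta-\varphi)}{D - r\cos(\beta-\varphi)}. $$

So per orbit and per first-region view the algorithm computes
$r\sin(\beta_1-\varphi)$ and $r\cos(\beta_1-\varphi)$ once (two trig
evaluations) and assembles the four distinct pairs

| pair | $U$ | $s'$ | serves (member, region) |
|------|-----|------|--------------------------|
| $P_0$ | $(D + r\sin)/D$ | $D r\cos/(D+r\sin)$  | $(E,\beta_1), (E_1,\beta_2), (E_2,\beta_3), (E_3,\beta_4)$ |
| $P_1$ | $(D - r\cos)/D$ | $D r\sin/(D-r\cos)$  | $(E_1,\beta_1), (E_2,\beta_2), (E_3,\beta_3), (E,\beta_4)$ |
| $P_2$ | $(D - r\sin)/D$ | $-D r\cos/(D-r\sin)$ | $(E_2,\beta_1), (E_3,\beta_2), (E,\beta_3), (E_1,\beta_4)$ |
| $P_3$ | $(D + r\cos)/D$ | $-D r\sin/(D+r\cos)$ | $(E_3,\beta_1), (E,\beta_2), (E_1,\beta_3), (E_2,\beta_4)$ |

Member $m$ in region $q$ uses pair $p = (m - q + 1) \bmod 4$. Four
geometry pairs thus cover sixteen (member, region) contributions. Relative
to the naive accounting (2 trig + 1 pair per pixel-view), the symmetry
algorithm performs exactly $1/4$ of the geometry-pair computations and
$1/16$ of the trig evaluations for even $n$ — one $\sin/\cos$ pair serves
4 members $\times$ 4 regions. Both ratios are instrumented by
`new_op_counter()` and asserted exactly in the test suite. The result is
*identical summands regrouped*: the symmetry and naive images agree to
floating-point regrouping error (observed $\sim 10^{-14}$ relative; the
tested contract is $10^{-6}$).

## The reconstruction chain

The quadrant-symmetry argument concerns only the back-projection
geometry. To make reconstructions quantitatively meaningful the package
wraps it in the standard flat-detector fan-beam FBP chain:

1. **Cosine pre-weight** — entry $(\beta, s)$ times $D/\sqrt{D^2 + s^2}$.
2. **Ram-Lak ramp filter** — row convolution with the discrete kernel
   $h(0) = 1/(4\Delta s^2)$, $h(m) = -1/(\pi^2 m^2 \Delta s^2)$ for odd
   $m$, zero otherwise, scaled by $\Delta s$; implemented by FFT with zero
   padding to the next power of two $\ge 2 n_\text{bins}$, so no circular
   wrap-around.
3. **Weighted back-projection** — accumulate
   $q(\beta, s')\,\Delta\beta / U^2$ (with $\Delta\beta$ in radians),
   linear interpolation between the two bins bracketing $s'$, zero
   contribution off the detector.

Because a full turn of fan-beam views measures every ray twice,
`reconstruct()` halves the filtered views before back-projecting; this is
the standard full-scan normalization and is what makes the uniform-disk
check recover a mean of 1.0 rather than 2.0.

### Geometric conventions

* At view angle $\beta$ the source sits at polar angle $\beta + 90^\circ$,
  distance $D$; $s$ is measured along $(\cos\beta, \sin\beta)$ on the
  virtual detector through the isocenter. This is the unique convention
  under which $s' \to r$ as $\beta \to \varphi$ and $s' \to 0$ as
  $r \to 0$, matching the mapping above.
* View angles are $\beta_k = k \cdot 360^\circ/n_\text{views}$,
  $k = 1..n_\text{views}$, so the four view regions are half-open on the
  left and $\beta = 360^\circ$ belongs to region 4. The symmetry method
  requires $n_\text{views}$ divisible by 4 and rejects anything else.
* The detector is flat and equispaced, centered at $s = 0$; with an odd
  bin count the middle bin is exactly the central ray.
* Pixel $(i, j)$ of an $n \times n$ grid has center
  $\big((j - \tfrac{n+1}{2})\,\Delta x,\ (\tfrac{n+1}{2} - i)\,\Delta x\big)$,
  so quarter turns permute pixel centers exactly, for odd and even $n$
  alike; for odd $n$ the center pixel is a singleton orbit handled by the
  naive rule ($U = 1$, $s' = 0$).
* Angles are degrees at every interface and converted to radians once on
  entry.

## Phantoms and the forward projector

No reference images ship with the package; everything downstream is
exercised on synthetic objects. `default_head_phantom()` is a
deterministic additive-ellipse phantom emulating a transverse head
section: a bright elliptical ring (skull), an interior tissue ellipse, a
ventricle-like depression, and two small high-contrast lesions, all
inside a unit bounding radius. `project_analytic()` produces exact
sinograms by closed-form line/ellipse chord lengths, which gives the
reconstruction chain an independent oracle; `project_numeric()`
(bilinear sampling along rays) covers grids with no analytic form and is
itself tested against the analytic projector.

What the generator emulates is the *geometry* of a head section — piecewise
constant structures at realistic scales and contrasts. What it does not
emulate: MR physics (k-space sampling, coil sensitivities, relaxation
contrast), anatomical texture, or correlated noise. Passing tests
therefore demonstrate correctness of the projection/reconstruction
mathematics, not clinical image quality on patient data. Optional
additive Gaussian noise (`add_noise()`, seeded) is the only noise model.

Default study conditions, used throughout tests and the acceptance
script: source distance $D = 4\times$ the object bounding radius; the
detector covers the fan shadow of the bounding disk with a 10% margin;
grids span the bounding box. Equivalence and counter checks run at
$n = 64$ with 360 views and 257 bins; the uniform-disk consistency check
at $n = 128$ with 720 views and 513 bins; these sizes exercise every code
path at interactive runtimes while keeping discretization error well
inside the 5% contract of the disk check.

## Image-quality metrics

`mse()`, `psnr()` and `ssim()` implement
$\mathrm{MSE} = \frac{1}{mn}\sum (I - K)^2$,
$\mathrm{PSNR} = 10\log_{10}(\mathrm{MAX}^2/\mathrm{MSE})$, and the
structural similarity index. Choices worth stating:

* **SSIM is global by default** (single window over the whole image,
  population $1/N$ variances, matching the MSE convention); the common
  sliding-window mean is available via `window =` but is explicitly
  non-default.
* Stabilizers follow the standard convention $c_1 = (0.01\,\mathrm{MAX})^2$,
  $c_2 = (0.03\,\mathrm{MAX})^2$.
* $\mathrm{MAX}$ is always an explicit argument — 255 for 8-bit exports,
  the data range for floating-point grids; identical images return the
  `Inf` PSNR sentinel rather than an error.
* Internal consistency pin: $\mathrm{MAX} = 255$ with
  $\mathrm{MSE} = 150$ evaluates to $26.370$ dB, and the test suite
  asserts exactly that; published (MSE, PSNR) pairs that disagree with
  this identity cannot be reproduced by any implementation of the formula.

## Trial statistics

`trial_stats` reproduces the self-contained clinical computations from
summary data. `riker_agitation_table()` carries the per-grade Riker SAS
counts of the two 30-patient groups. Two conventions are inferred and
documented rather than guessed silently:

* **Agitation cut at grade ≥ 5.** The scale's standard semantics (5 =
  agitated) and the only threshold that reproduces both published
  incidences simultaneously.
* **Truncation, not rounding, to whole percent.** $5/30 = 16.67$ and
  $23/30 = 76.67$ print as 16 and 76, so the incidence uses `trunc()`.

`chi_square_2x2()` uses the closed-form Pearson statistic without
continuity correction by default (expected counts here are all $\ge 14$);
Yates is a flag. `two_sample_t()` works from mean/SD/n in pooled or Welch
form, since only summary statistics are published. All three are
cross-checked in the tests against `stats::chisq.test()` /
`stats::t.test()` as independent oracles.

## Numerical choices and edge cases

* Linear interpolation at $s'$; zero outside detector support.
* $r \ge D$ is rejected (the $1/U^2$ weight would blow up at $U = 0$);
  grid/geometry combinations whose corner pixels reach the source circle
  are rejected as incompatible.
* The symmetry accumulator writes per-orbit contributions member by
  member; summation order differs from the naive loop, hence the
  $10^{-6}$ relative equivalence contract rather than bit-identity.
* The quarter-turn identity tests compare values to $10^{-12}$ relative
  with a unit floor on the scale (a pure relative comparison is
  ill-defined where $\sin$ or $s'$ crosses zero).
* View-count robustness (more views cannot hurt noiseless FBP) is checked
  at 720 vs 90 views; the 90-view reconstruction uses the naive
  back-projector, since 90 is not divisible by 4 and the symmetry method
  (by design) refuses it.
* PGM export is plain (P2) ASCII with the affine intensity scaling
  recorded in a header comment, so the mapping is invertible; text grid
  and sinogram formats round-trip at full double precision.

## Known limitations

* 2-D only; flat equispaced detector only (no curved-detector variant,
  no cone beam).
* The acceleration reorganizes *computation*, not *sampling*: it changes
  no pixel value and therefore cannot improve image quality by itself;
  quality claims in this package are always about the FBP chain as a
  whole against rasterized ground truth.
* No iterative or sparsity-regularized reconstruction: the implemented
  algorithm is a symmetry-accelerated weighted back-projection, and the
  quality metrics evaluate exactly that.
* The trial-statistics module covers the summary-statistic computations
  that published tables support; patient-level trajectories are out of
  scope.

## A worked example

```{r example, eval = FALSE}
ph <- default_head_phantom()
g  <- fan_geometry(D = 4, n_views = 360, n_bins = 257,
                   bin_spacing = 2 * 1.1 * (4 / sqrt(15)) / 257)
sino <- project_analytic(ph, g)
rec  <- reconstruct(sino, n = 64, pixel_size = 2 / 64, method = "symmetry")
truth <- rasterize(ph, 64, 2 / 64)
quality_report(truth, rec$image, max_val = max(truth$values))
rec$counter
```
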