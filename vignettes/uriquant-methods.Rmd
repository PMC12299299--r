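---
title: "Methods: from dipstick image to concentration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from dipstick image to concentration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uriquant)
```

## The problem

Urine dipsticks carry reagent pads whose post-reaction color encodes the
concentration of one analyte each. Conventional readers are
semi-quantitative: they match the pad color to the nearest block on a printed
colorimetric card (levels `-`, `-+`, `+`, `++`, `+++`, `++++`). `uriquant`
implements a fully quantitative route: extract a mean RGB per pad from a
strip image, correct device color bias, and regress concentration from the
corrected color with a small neural network whose initial weights are chosen
by the whale optimization algorithm (WOA). The package also retains the
semi-quantitative card-matching route, since it is the clinical baseline.

## Color representation

Device RGB is converted to CIELab through the standard sRGB (D65) pipeline:
8-bit channels are divided by 255, gamma-expanded (`u/12.92` below 0.04045,
`((u+0.055)/1.055)^2.4` above), mapped through the sRGB matrix to XYZ,
divided by the reference white `(0.95047, 1, 1.08883)`, and compressed with
`f(t) = t^(1/3)` for `t > 0.008856` and `f(t) = (903.3 t + 16)/116` below.
The two-branch `f` is continuous at the threshold (both branches give
≈ 0.2069), which is why the low-`t` slope constant 903.3 pairs with the
cube-root branch. One numerical subtlety: the conventional 7-digit sRGB
matrix rows do not sum *exactly* to the reference white (the middle row sums
to 1.0000001), which would leave achromatic colors with residual chroma of
about 1e-5. We rescale each row (a relative change below 1e-7) so that gray
inputs map to exactly `a* = b* = 0`.

Color difference is CIE76, the Euclidean distance in Lab. Card matching
returns the level with the smallest distance; ties break toward the earliest
(lowest) level in card order — the clinically conservative choice, since it
never over-reports. `lab_to_rgb()` is the exact algebraic inverse, clipping
out-of-gamut results to [0, 255] with a flag rather than an error.

## Device color correction

Device bias is corrected per channel in CIELab: for each of L, a, b a
polynomial `x_ref = a0 + a1 x + ... + an x^n` is fitted by least squares
against a measured/reference chart (default degree 2, supported 1–4, via
`stats::lm` on raw polynomial terms). Cross-channel (3×3 or 3D-LUT)
correction is deliberately out of scope: three univariate polynomials are
what a small fixed-illumination reader can support and validate. Residual
RMS per channel is stored as the fit diagnostic; since the model classes are
nested, RMS is non-increasing in the degree. Inputs outside the chart's
fitted range are extrapolated but flagged with a warning — polynomials
diverge quickly outside the fit support. Chart size is not standardized
here; the test fixtures use a 24-patch layout typical of standard cards.

## Reflectance theory

For an optically thick pad, Kubelka–Munk theory ties diffuse reflectance R
to the absorption/scattering ratio, `K/S = (1 - R)^2 / (2R)`, and
Beer–Lambert makes absorption proportional to concentration, `K = εC`, so
`C = S (1 - R)^2 / (2 R ε)`. The module encodes these relations exactly
(including the closed-form inverse `R = 1 + ks - sqrt(ks^2 + 2 ks)`), and
they explain *why* darker pads mean more analyte; but the package makes no
attempt to estimate ε or S from images. Cameras see color, not calibrated
reflectance, so the quantitative bridge from color to concentration is
empirical — the calibration curves and the regression network below.

## Calibration curves and synthetic data

The built-in curve sets are published least-squares fits of channel value
against concentration: double-exponential-with-offset forms for urinary
protein (range 0–500 mg/dL) and logistic/Hill forms for leukocytes. They are
treated as printed constants; the raw card measurements behind them are not
public, so refitting is a non-goal.

Two caveats are worth stating plainly. First, the protein C–B curve as
printed contains the term `-707813.13 exp(-C/1.39)`, whose decay constant
makes the curve leave [0, 255] for any concentration above roughly
0.2 mg/dL; after the generator's mandatory clipping the B feature saturates
at 255 over essentially the whole range and carries no information. The
regression therefore effectively rests on the R and G channels (which is
also what the measured validation table suggests — its B column behaves
quite differently from the printed curve). Second, the leukocyte fits come
with no printed units or physiological range; the package uses the same
[0, 500] span as the protein set, in curve-domain units, and flags it as
such.

`generate_dataset()` samples concentrations uniformly over the curve range
(uniform for coverage, since no sampling scheme is published), evaluates the
three curves, optionally adds Gaussian channel noise (default 0 — the
published construction is a deterministic curve inversion), clips to
[0, 255], and splits 500 training / 70 test rows after a seeded shuffle.

## The BP network and its training

The regressor is a feed-forward network, default topology 3-10-1: sigmoid
hidden units, identity output. Since the published work never prints its
chosen topology, 10 hidden units were fixed as a mid-range default (the
dimension of the weight/threshold vector is then 51). Features and target
are min-max scaled to [0, 1] with statistics fitted on the training split
only. A column that is constant on the training split (the saturated B
channel) is recorded as degenerate and scaled to 0 for *any* input, so the
network ignores the dead feature instead of receiving wild extrapolations
when a real measurement deviates from the saturated value.

Training is plain full-batch gradient descent on the MSE via
backpropagation; the analytic gradient is verified against central finite
differences in the test suite. Defaults: learning rate 0.1, 4,000 epochs.
The epoch budget was chosen so that the default run reaches the accuracy
regime the published device reports on the noiseless 500/70 protein task
(test MAE under 10 mg/dL; about 2 s of compute); a 1,000-epoch budget
leaves the same network a factor of ~4 short in MAE. Weights initialize uniformly in
[-0.5, 0.5] (symmetric small values, standard for sigmoid nets), thresholds
at zero.

## The whale optimization algorithm

WOA treats each candidate weight/threshold vector as a whale position. Per
iteration and whale, with `a` decaying linearly from 2 to 0 and scalar draws
`r, p ~ U[0,1]`, `l ~ U[-1,1]`:

* encircling (`p < 0.5`, `|A| < 1`): `D = |C X* - X|`, `X ← X* - A D`;
* searching (`p < 0.5`, `|A| ≥ 1`): as above with a random whale in place
  of the best — this is the exploration phase;
* spiral (`p ≥ 0.5`): `X ← |X* - X| e^{bl} cos(2πl) + X*`,

with `A = 2ar - a`, `C = 2r`, spiral constant `b = 1` (no published value).
Three printed ambiguities are resolved on the side of the canonical
algorithm and the source's own prose: the decay is the linear
`a = 2(1 - t/T_max)` ("decreases linearly from 2 to 0"), the exploration
update uses the random whale the text describes (the printed equation
repeats the exploitation form), and `r`, `A`, `C`, `p`, `l` are drawn once
per whale per iteration as scalars shared across dimensions — the simplest
reading that reproduces the scalar formulas. Positions are hard-clipped to
the search box (default [-3, 3] per dimension) after every sweep, and the
best-so-far is updated once per sweep, giving a monotone non-increasing
fitness history. Population 30 and 50 iterations are desk-scale defaults;
neither is published. PSO (inertia 0.72, cognitive/social 1.49) and a
real-coded GA (tournament k = 3, BLX-0.5 crossover at 0.9, Gaussian
mutation with σ = 5% of range at 0.1, one elite) are provided as the
comparison baselines under the identical interface.

The WOA-BP pipeline runs the metaheuristic on the training-MSE fitness over
flat parameter vectors, then uses the best vector to *initialize* gradient
descent. Refinement starts exactly at the optimizer's best fitness and, with
the default step size, never ends worse — this is monitored by a test. The
`optimizer = "none"` mode trains from random initialization with the same
budget, which is the ablation used to show the ordering (WOA-initialized
final loss ≤ plain BP in at least 7 of 10 seeded trials; in practice 10/10).

## The synthetic strip imager and the processing chain

The generator renders a horizontal strip: 11 square reagent pads (40 px) on
a light plastic carrier (gray 230), i.i.d. Gaussian sensor noise (σ = 5 by
default), and one localized elliptical-Gaussian specular highlight
(amplitude 80). Real reagent pads are matte paper while the carrier is
glossy plastic, so the default highlight sits on the carrier between the
strip edge and the pad row. Output is quantized to 8 bits and fully
reproducible from a seed.

Processing runs: 5×5 Gaussian smoothing (σ = 1); highlight suppression as
the weighted superposition `0.6·image + 0.4·blur(image)` (no published
weight; 0.6 keeps pads essentially unchanged while attenuating speculars);
luma grayscale (0.299/0.587/0.114, the conventional weights); Otsu
binarization implemented from the between-class-variance definition
(classes [0, T-1] / [T, 255], exhaustive over T, smallest maximizer on
ties), with the carrier identified as the gray class dominating the image
border; 3×3 elliptical opening then closing (EBImage); Canny edge
extraction (Sobel, non-maximum suppression, 50/150 hysteresis — written
here, as EBImage has none); connected pad regions; and finally the mean RGB
over a 15×15 patch at each pad's edge-bounding-box center, computed on the
pre-binarization color image (whether the published chain samples before or
after binarization is unstated; sampling the smoothed color image is the
information-preserving choice). Pads are reported left to right regardless
of detection order.

What the generator does *not* emulate: perspective and rotation, uneven
illumination fields, strip-type variation, and pads whose luma approaches
the carrier's. The last one is a genuine operating limit of this classical
chain: a single global threshold cannot keep a near-carrier-bright pad in
the foreground class (the production system described alongside these
methods used a learned detector for exactly this reason, and that detector
is out of scope here). The test harness therefore samples reacted-pad
colors in the mid-tone envelope (channels 40–160 against carrier 230),
where detection is reliable with margin — passing tests certify the chain
inside that envelope, not on arbitrarily pale pads.

## Numerical conventions and degenerate inputs

* Channel range errors name the offending channel; conversions are all in
  double precision, with rounding only at image export.
* Otsu on a constant image is a degenerate-input error; `process_strip()`
  converts it (and a pad-free segmentation) into an empty result with a
  warning.
* A σ_b² plateau (empty gray gap between classes) is resolved to the
  smallest maximizing threshold; the EBImage cross-check in the tests
  therefore compares attained variance, not threshold index.
* Sampling patches that would cross the image border are skipped with a
  warning naming the pad.
* `compute_metrics()` defines R² against the true-value mean and reports
  per-sample relative errors as `100(ŷ - y)/y`, undefined (NA) at `y = 0`.
* Metric agreement with published values is asserted to 4 significant
  digits, their print precision.

## Problem sizes used by the tests

The suite runs entirely on synthetic data built at test time: the 500/70
protein task for end-to-end checks, 200 random histograms against the
exhaustive Otsu oracle, 1,000-color conversion round trips, 50 random strip
layouts (noiseless) plus 50 noisy highlighted strips for the image chain,
sphere benchmarks in 5 dimensions, and 10-seed ordering trials at a reduced
800-epoch budget (the ordering is about initialization quality, not final
polish). These sizes keep the whole suite under a minute while leaving the
statistical margins wide (worst observed pad-color deviation is about
1/channel against a 3/channel tolerance).

## Known limitations

* The quantitative route is validated against synthetic data generated from
  the published calibration curves; no raw instrument data are public.
* The printed protein C–B coefficients are unusable away from C ≈ 0 (see
  above); the package reproduces them faithfully rather than repairing them.
* Leukocyte units are undefined in the source material.
* The classical localization chain assumes mid-tone pads on a light
  carrier; pale pads need a learned detector, which is out of scope.
* No uncertainty quantification: predictions are point estimates clipped to
  the analyte range.
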