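---
title: "Single-TI Bloch-model T1 mapping: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-TI Bloch-model T1 mapping: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refblochi)
```

## The problem

High-resolution 3D post-contrast T1 maps of the heart are valuable for
characterizing diffuse fibrosis in thin-walled structures (left atrium,
right ventricle) where 2D mapping sequences suffer from partial voluming.
Conventional T1 mapping needs several inversion times and therefore
several long 3D acquisitions. This package implements a single-TI
alternative: one 3D late-gadolinium-enhancement (LGE) inversion-recovery
FLASH volume is transformed voxel-by-voxel into a T1 map using an exact
Bloch-equation steady-state signal model, one reference T1 (typically
blood, measured by a fast 2D scan), and removal of coil shading by
polynomial detrending.

## Signal model

The LGE sequence applies, every `RR` interval: an inversion pulse, a
recovery of `TI` ms, a train of `N` readout pulses of flip angle `alpha`
spaced `TR` ms apart, and free recovery for the remainder of the
interval. The measured voxel signal is proportional to the longitudinal
magnetization just before the first readout pulse (centric phase-encode
ordering), in periodic steady state:

$$
M_{zss} = M_0\,\frac{1 - 2\,e^{-TI/T_1} + p\,e^{-RR/T_1}}
               {1 + \cos^N\!\alpha\; e^{-RR/T_1}},
$$

where $M_0$ collects proton density, $T_2^*$ weighting, coil sensitivity
and global gain, and $p \ge 1$ is the *perturbation coefficient*: the
factor by which the readout train raises the recovered magnetization
relative to the classical two-exponential inversion-recovery model
(`mzss_simple()`). With $E = e^{-TR/T_1}$ and $Q = E\cos\alpha$,

$$
p = \frac{1 - (1-E)\,\frac{1-Q^N}{1-Q}}{E^N},
$$

with $(1-Q^N)/(1-Q) \to N$ as $Q \to 1$. This closed form was derived
from the periodic steady state of the pulse sequence and is accepted in
this package only because it agrees with an independent discrete Bloch
recursion (`bloch_steady_state()`, iterated to a $10^{-13}$
period-to-period tolerance) to better than $10^{-9}$ over randomized
protocols; the same recursion validates the no-inversion model
(`mzss_noinv()`) used by the multi-TI fit and the imperfect-inversion
model (`f_imperfect()`), in which an inversion of efficiency
$\beta \in (0,1]$ multiplies $M_z$ by $-\beta$.

Two timing conventions were genuinely open and are fixed as follows:
each readout pulse is followed by a full `TR` of relaxation, and the
free-recovery interval is `RR - TI - N*TR`. This convention reproduces
the denominator $1 + \cos^N\!\alpha\,e^{-RR/T_1}$ exactly; the
alternative (no relaxation after the last pulse) differs only in how $p$
is expressed.

For the TI $\approx$ 300 ms protocols used post-contrast, the weighting
$f(T_1) = M_{zss}/M_0$ is strictly decreasing over the whole 100–800 ms
search range — this monotonicity is what makes the signal-to-T1
relationship one-to-one. $f$ is *positive* over the 200–600 ms
post-contrast range for the simulation and phantom protocols
(RR $\le$ 950 ms), so magnitude data need no polarity restoration there;
the null point sits near 740–790 ms for RR = 900 ms and moves down to
about 600 ms by RR = 1000 ms, which is why the grid search reports
boundary flags rather than assuming positivity everywhere.

## Single-point calibration and grid search

Given a reference tissue of known T1 (blood: homogeneous, easy to
delineate, and with a T1 intermediate between myocardium and scar), the
scalar $M_0$ is the measured reference signal divided by $f(T_1^{ref})$
(`estimate_m0()`). The reference signal is the *mean* over the
user-supplied ROI after detrending (the choice between mean and median
was open; the mean is the usual ROI statistic and is what the noiseless
self-consistency tests assume). Each voxel is then inverted by
minimizing $|S - M_0 f(T_1)|$ over a 100–800 ms grid with 2.5 ms
density. Numerical conventions:

* ties break toward the smaller T1 (deterministic, and conservative for
  scar detection);
* estimates that land on a grid endpoint are *flagged, not discarded* —
  downstream QC decides;
* non-finite voxels are marked invalid and skipped, never fatal;
* the model curve is evaluated once per protocol and reused for every
  voxel (provably identical to per-voxel evaluation).

## Coil detrending

Coil shading is removed by fitting the full trivariate cubic polynomial
(20 monomials $x^iy^jz^k$, $i+j+k\le3$) to the intensities of a
non-contiguous VOI placed in the blood pool, then dividing the
extrapolated trend out of the volume. Ordinary (unweighted) least
squares is used — no weighting scheme is part of the method — on
coordinates normalized to $[-1,1]$ per axis over the volume bounding
box, which conditions the 20-term design. The fit refuses VOIs with
fewer than 100 voxels (five per coefficient) or degenerate geometry
(e.g. coplanar voxels make the design rank-deficient), and the
extrapolated trend must be strictly positive over the detrending region:
a cubic can change sign far from the VOI, and a silent sign flip would
corrupt the map. Detrending is fitted fully in 3D (not per slice).

## Multi-TI comparison fit

The comparison method acquires three inversion-prepared volumes at
distinct TIs plus one volume with the inversion disabled, and estimates
$(T_1, M_0)$ per voxel by bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) on the joint residual of the inversion model at
each TI and the no-inversion model. Starts are deterministic: T1 from
{200, 400, 700} ms in order (first convergent start wins), $M_0$
started at the no-inversion signal, which approximates $M_0$ near full
recovery; T1 is boxed to [50, 2000] ms. No registration between the
four volumes is attempted. Magnitude data are fitted with the signed
model; at TI = 100 ms a long-T1 voxel's true $M_z$ can be negative
while its magnitude is positive, so voxels whose best fit prefers
negative model values are flagged (`neg_model`) rather than silently
de-rectified. The $M_0$ map, normalized to the blood-pool mean
(`m0_ratio_map()`), is how the near-uniformity assumption of the
single-TI method is checked.

## Error analysis

Four error sources matter. Two bias the calibration only (Category 1:
a wrong reference T1; M0 heterogeneity between tissues); two bias the
signal model itself (Category 2: a wrong effective RR; imperfect
inversion). Writing $\delta$ for the ratio of estimated to true $M_0$
at the affected voxel, the first-order biases are

$$
\Delta T_1 \approx \frac{(1-\delta)\,f(T_1)}{\delta\,f'(T_1)}
\qquad\text{and}\qquad
\Delta T_1 \approx \frac{f^{true}(T_1)-\delta\,f(T_1)}{\delta\,f'(T_1)} .
$$

$f'$ is computed by central finite difference with a 1 ms step ($p$
depends on T1, making the symbolic derivative error-prone; 1 ms is well
below the 2.5 ms grid); at the domain boundary a one-sided difference is
used and flagged. `simulate_bias()` checks these formulas against the
actual pipeline: generate noiseless signals under the scenario's truth
model, calibrate with the scenario's (wrong) reference or model, invert
by grid search. True T1s are evaluated on the grid resolution
(200–600 ms in 2.5 ms steps) so the curves measure model bias rather
than quantization.

A known limitation, computed by the test suite: the first-order
Category-2 formula deviates from direct simulation by more than 5 ms
(up to about 7 ms) beyond T1 $\approx$ 550 ms under the worst-case
imperfect inversion ($\beta = 0.92$), where the bias itself approaches
50 ms — the expansion error grows quadratically with the bias. The
M0-heterogeneity, reference-T1 and RR scenarios agree within about
2–4 ms everywhere in 200–600 ms.

## Monte-Carlo precision

`monte_carlo_precision()` draws, per condition, `n_reps` replicates of
$f(T_1) + \mathcal{N}(0, \sigma)$ with $\sigma$ = (blood signal at the
280 ms reference)/SNR, inverts each by the same grid search the mapper
uses (the method's defined inversion — not a continuous solver), and
reports the SD. Three conventions deserve note:

* the calibration uses the *noiseless* reference signal — a noisy
  reference would conflate calibration error with voxel noise and
  change the shape of the SD-versus-T1 curve;
* noise is real additive Gaussian on the signed signal (a Rician
  magnitude mode exists in the phantom generator for realism studies,
  but the precision analysis models the signed signal);
* replicates clipped at the grid bounds are *included* in the SD —
  exclusion would report an optimistic precision for exactly the voxels
  most affected by noise.

Precision degrades with T1 (since $|f'|$ decreases) and improves with
SNR; the RR dependence is comparatively small.

## The phantom generator

`generate_phantom()` emulates what the method needs from data and no
more: per-compartment T1s spanning the post-contrast range, an $M_0$
composition $A \cdot PD \cdot e^{-TE/T_2^*}$ per compartment (defaults
give myocardium/blood $\approx$ 1.03 and scar/blood $\approx$ 0.94, the
in vivo scale of proton-density/T2* heterogeneity; proton densities sit
in the 0.76–0.84 water-content range), a strictly positive smooth coil
field (the exponential of a seeded random low-order polynomial), and
Gaussian (default) or Rician noise at a stated blood SNR. The cardiac
geometry is schematic — nested blood pool, myocardial shell, scar
sector — because the mapper is voxel-wise: geometry exercises only
detrending and masking. The tube phantom uses six T1s evenly spaced in
200–560 ms (the individual values of the physical tubes are not
published; even spacing covers the same range). Consequently, passing
tests demonstrate correctness of the estimator under the modeled
conditions; they say nothing about partial voluming, motion, flow,
magnetization transfer, off-resonance or k-space effects, which the
generator deliberately does not model.

## Problem sizes and runtime choices

The test suite runs phantoms of 12–48 voxels per side, 120-replicate
noise comparisons for the multi-TI fit, and 800–10,000-replicate
Monte-Carlo runs; the full suite completes in a few seconds. The
acceptance script re-runs the four precision conditions at the full
10,000 replicates and the three bias sweeps at 2.5 ms resolution in
under a second. These sizes were chosen so the estimator's asymptotic
behavior (e.g. the ~9 ms noise-induced skew of tube means at blood-SNR
20 near T1 = 560 ms) is resolved well above sampling error.

## Known limitations

* Pre-contrast (native) T1 mapping is out of reach for the single-TI
  method: at native T1s the signal-T1 curve is no longer guaranteed
  monotone-positive for practical TIs, and the blood reference logic
  changes; `ecva()` therefore uses assumed native T1s (1150 ms
  myocardium, 1500 ms blood, HCT 0.45 by default). Raising the assumed
  native myocardial T1 by 100 ms shifts ECVa by a constant
  +0.0175 ($\approx$ +0.02) independent of the post-contrast
  myocardial T1, which bounds the cost of assuming a population value.
* ECVa is reported unclamped; values above $1-HCT$ can occur in
  pathology and are meaningful QC signals.
* The grid search bounds estimates to [100, 800] ms; boundary flags
  must be inspected when mapping tissues near either end.
* The first-order bias formulas are screening tools; near worst-case
  Category-2 errors at long T1 they understate/overstate the simulated
  bias by several ms (see above).
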