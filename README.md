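# refblochi

Single-inversion-time post-contrast T1 mapping for 3D cardiac MRI.

## What it does and who it is for

High-resolution 3D T1 maps of the heart are needed to assess diffuse
fibrosis in thin-walled structures (left atrium, right ventricle) where
2D mapping sequences are limited by partial voluming — but conventional
T1 mapping multiplies scan time by acquiring several inversion times.
This package implements a single-TI method for post-contrast T1 mapping:
one 3D late-gadolinium-enhancement (LGE) inversion-recovery FLASH volume
is transformed directly into a voxel-wise T1 map using

1. an exact Bloch-equation steady-state model of the LGE signal,
2. a single-point calibration against one reference tissue of known T1
   (typically the blood pool, measured by a fast 2D scan), and
3. cubic-polynomial detrending of coil-sensitivity shading fitted over a
   blood-pool VOI.

It is intended for quantitative-MRI researchers and image-analysis
pipelines working with post-contrast cardiac LGE data, and for anyone
studying the accuracy/precision trade-offs of single-point-calibrated
relaxometry.

## The model

The steady-state signal just before the first readout pulse of an
inversion-recovery FLASH segment (inversion, recovery TI, N pulses of
flip angle α spaced TR apart, free recovery to RR) is

    M_zss = M0 · (1 − 2 e^{−TI/T1} + p e^{−RR/T1})
                 / (1 + cos^N(α) e^{−RR/T1})

where M0 collects proton density, T2*-weighting, coil sensitivity and
gain, and p ≥ 1 is the perturbation coefficient of the readout train:
with E = e^{−TR/T1}, Q = E cos α,

    p = [1 − (1−E)(1−Q^N)/(1−Q)] / E^N .

For the TI ≈ 300 ms protocols used post-contrast this weighting is
strictly decreasing in T1, so signal↔T1 is one-to-one: calibrating the
scalar M0 from one reference tissue lets a grid search (100–800 ms,
2.5 ms density) invert every voxel. All closed forms are validated in
the test suite against an independent discrete Bloch recursion run to
steady state. The package also provides the multi-TI joint
(T1, M0) least-squares comparison fit, analytic + simulated bias curves
for the method's four major error sources, Monte-Carlo precision
analysis, an ECV approximation from assumed native T1s, and a synthetic
phantom generator with full ground truth.

## Worked example

Simulate a cardiac-like phantom with coil shading and noise, detrend,
calibrate on blood (T1 = 280 ms), and map:

```r
library(refblochi)

prm  <- seq_params(tr_ms = 5, flip_deg = 15, ti_ms = 300,
                   rr_ms = 900, n_views = 33)
spec <- phantom_spec(geometry = "cardiac", dim = c(32, 32, 8),
                     coil = "polynomial", noise = "gaussian", snr = 20,
                     protocol = prm, seed = 7)
ph   <- generate_phantom(spec)
voi  <- ph$truth$labels == 1        # blood pool: detrending VOI + reference
fit  <- refblochi(ph$image, prm, ref_t1_ms = 280, ref_roi = voi,
                  mask = ph$truth$labels > 0, voi = voi)
summary(fit)
```

```
Single-TI Bloch-model T1 map (refblochi)
IR-FLASH protocol: TR/alpha/TI/RR/N = 5 ms/15 deg/300 ms/900 ms/33
  M0 = 2.76138 (ref T1 280 ms)
  voxels: 4480 mapped / 0 boundary / 0 invalid
  T1 (ms) quantiles:
   0%   25%   50%   75%  100%
207.5 275.0 287.5 440.0 527.5
```

Per-compartment recovery against the generator truth:

```
blood      true 280 ms  mapped 280.2 +/-  8.5 ms
myocardium true 450 ms  mapped 447.9 +/- 20.7 ms
scar       true 220 ms  mapped 231.2 +/-  6.9 ms
```

Blood (the reference) and myocardium are recovered essentially
unbiased; the ~11 ms scar offset is the expected Category-1 effect of
the phantom's deliberate M0 heterogeneity (scar carries 0.94× the blood
weighting, and a 6% calibration mismatch biases short T1s by about
this much — the bias formulas in `bias_category1()` predict it). The
larger spread at 450 ms reflects the |f′| decrease with T1: precision
degrades for longer T1s. An ECV estimate for a voxel at 450 ms with
280 ms blood:

```r
ecva(450, 280)
#> [1] 0.2562602
```

A command-line front end wrapping the same functions ships in
`inst/cli/refblochi` (subcommands `simulate`, `detrend`, `map`,
`multiti`, `ecv`, `bias`, `precision`; see `refblochi help`).

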