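---
title: "Activation mapping and conduction velocity estimation on 60-electrode MEAs"
author: "MEAflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activation mapping and conduction velocity estimation on 60-electrode MEAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MEAflow)
```

## The problem

Cultured excitable monolayers — here, spontaneously beating cardiomyocyte
sheets — conduct excitation as a continuous medium. A planar microelectrode
array (MEA) records the extracellular field potential (FP) at 60 sites on an
8×8 grid with the four corners absent, 200 µm apart. Two quantities
summarise each propagating wavefront:

* the **activation time** at each electrode: the moment the wavefront passes,
  operationalised as the time of the steepest negative voltage slope
  (dV/dt minimum) of the FP downstroke;
* the **conduction velocity (CV)**: speed and direction of propagation.

Naive two-electrode CV estimates (Δdistance/Δtime along a hand-picked
direction) are subjective and blow up when the chosen electrode pair is
nearly perpendicular to the true propagation direction. MEAflow instead fits
a smooth activation-time *surface* over the whole array and differentiates
it — the Bayly method — which needs no direction to be chosen, is robust to
missing electrodes, and supplies residual-based quality diagnostics.

## The model

With electrode coordinates $(x, y)$ in µm and activation times $t$ in ms,
the activation surface is the quadratic

$$T(x, y) = a x^2 + b y^2 + c x y + d x + e y + f,$$

fitted by ordinary least squares to all non-silenced electrodes with a
detected time (at least 6 are required; 6 exactly determine the surface).
The velocity vector at an electrode is

$$\mathbf{V} = \frac{(T_x,\; T_y)}{T_x^2 + T_y^2},
  \qquad T_x = \partial T/\partial x,\; T_y = \partial T/\partial y,$$

so that $\mathbf{V}\cdot\nabla T = 1$ — the wavefront advances down the
time gradient at speed $1/|\nabla T|$. With $T_x, T_y$ in ms/µm the speed
comes out in µm/ms, numerically equal to mm/s; the package reports mm/s
everywhere. The mean local CV is the arithmetic mean of the per-electrode
speeds over the electrodes where the gradient is non-degenerate.

### Numerical choices

* **Conditioning.** Raw µm² design entries are ~10⁶, so coordinates are
  centred and scaled to unit RMS before solving; coefficients are
  back-transformed. The solver is minimum-norm least squares via SVD —
  the problem is linear and needs no iterative optimiser. Rank-deficient
  designs (e.g. all electrodes on one line) warn and return the
  minimum-norm fit.
* **Degenerate gradients.** Electrodes with $|\nabla T| <$ 10⁻¹² ms/µm are
  flagged undefined and excluded from the mean speed rather than silently
  producing huge vectors.
* **One surface per window.** A single global quadratic is fitted per
  analysis window (one wavefront); local/windowed variants of the method
  are deliberately out of scope.

## Detection

Traces are smoothed once, at load time, with a Savitzky–Golay filter
(least-squares polynomial mid-point smoother), default order $N = 3$ and
half width $M = 50$ data points (101-point frame; at 20 kHz that is a
5.05 ms window). The predicted normalized cutoff of this smoother is

$$f_c = \frac{N + 1}{3.2 M - 4.6},$$

which evaluates to $4/155.4 \approx 0.02574$ at the defaults. `cutoffHz()`
converts to Hz against the Nyquist frequency by default (the standard
meaning of a normalized cutoff $\omega_c/\pi$); a `convention = "fs"`
option multiplies by the sampling rate instead, for compatibility with
tools that report the conversion that way.

**Edge handling** is not standardised across implementations; MEAflow fits
the order-$N$ polynomial to the largest available truncated window at each
edge position. This preserves exact polynomial reproduction (up to order
$N$) at *every* point, at the cost of higher noise amplification in the
outermost $M$ samples — which is why the beat detector ignores threshold
crossings inside the edge-transient region.

The activation time is the sample minimising the numeric gradient (central
differences at interior points, one-sided at the ends) of the smoothed
trace within the analysis window, ties broken toward the earliest sample.
No sub-sample interpolation is performed: resolution is one sample, and
detection is exactly the brute-force argmin of the gradient series, which
the test suite verifies on 1 000 random traces. A non-negative minimum
slope (no downstroke in the window) is returned but flagged, so users can
silence such electrodes — mirroring the inspect-and-silence workflow of
interactive MEA tools.

**Beat detection** extends the same dV/dt feature into an event detector:
gradient excursions below $-k$ robust SDs (default $k = 5$) of the
gradient series, keeping the steepest point per 100 ms refractory period.
The threshold is relative, so event times are invariant to trace rescaling.
This detector is a pragmatic extension — beats-per-minute quantification is
usually done by eye on trace plots — and is not meant as a validated
arrhythmia tool.

## The synthetic wavefront generator

All tests run against simulated recordings with exact ground truth. The FP
template is the biphasic waveform

$$g(\tau) = -A\,\frac{\tau}{w}\,\exp\!\left(\frac{1 - (\tau/w)^2}{2}\right),$$

one positive lobe then one dominant downstroke, with peak amplitude $A$
(default 500 µV, a typical neonatal cardiomyocyte FP scale) at
$\tau = \pm w$ (default $w$ = 1 ms) and — by construction — a unique
steepest-descent point exactly at $\tau = 0$, so the ground-truth
activation time is analytic. Wavefronts are planar (constant speed and
direction), focal (isotropic spread from a point, the corner-initiation
pattern of an edge pacemaker), or directly quadratic in the fitted model
class. Noise is white Gaussian, scaled per electrode to a multiple of the
clean trace's robust SD.

What the generator does **not** emulate: baseline drift and 50/60 Hz
interference, electrode-specific noise and impedance variation, waveform
heterogeneity across the culture, repolarisation waves, curved anisotropic
propagation, and reentry. Passing tests therefore demonstrate correctness
of the *computational* chain (smoothing → detection → fitting →
differentiation), not performance on any particular biological recording.

### Robust SD and the noise level

Noise levels and beat thresholds are defined against the robust SD
(1.4826 × median absolute deviation). A synthetic trace whose baseline is
*exactly* flat for most of its length has MAD ≈ 0, which would make a
relative noise level meaningless; when the MAD is negligible against the
plain SD (< 10⁻⁶ of it) the plain SD is used instead. Real recordings,
whose baseline carries instrument noise, always take the MAD branch.

## Robustness experiments

* **Dropout** (`dropoutCurve()`): silence $n$ random electrodes, refit,
  recompute mean CV, expressed as percent of the best estimate (all
  electrodes). On exactly-quadratic data the curve is flat at 100% for any
  subset of ≥ 6 electrodes in general position — the fit interpolates its
  own model class — so the informative experiment adds activation-time
  noise (SD 0.1 ms) and watches the *spread* of percent-of-best grow with
  $n$. Replicates draw without replacement within a replicate,
  independently across replicates, seeded.
* **Noise** (`noiseCurve()`): add white noise at levels given in robust-SD
  multiples (the "+4"-style absolute units seen in some reports are
  instrument-dependent; a scale-free multiplier is reproducible and
  preserves the intended ordering), re-smooth, re-detect, refit; report
  mean |Δ activation time| and |Δ mean CV| against the clean analysis,
  mean ± SEM (SD/√reps, 5 replicates by default). Level 0 is exactly zero
  by construction. Detection still returns a time everywhere even at level
  200 — the argmin always exists — the errors just become large.

### A measured limitation: sample-exact detection under noise

The template's gradient extremum is locally flat:
$g'(\tau) \approx g'(0)\,(1 - 1.5(\tau/w)^2)$, so one 20 kHz sample
(0.05 ms) away from the true activation time the gradient differs by only
~0.4% of its peak (at $w$ = 1 ms). Any noise that survives smoothing
therefore displaces the argmin by a few samples; measured across seeds,
noise at one tenth of the trace's robust SD yields median timing errors of
~0.02–0.05 ms but worst-case errors of ~0.1–0.2 ms (2–4 samples), and
heavier smoothing widens the plateau and makes it worse. Sample-exact
detection should be expected only on noise-free or very-high-SNR
downstrokes; the CV estimate is far less sensitive because the surface fit
averages timing noise over up to 60 electrodes.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `smoothing.order` | 3 | — | cubic preserves downstroke shape |
| `smoothing.halfWidth` | 50 | samples | 101-point frame at 20 kHz |
| detection tie-break | earliest | — | determinism |
| `thresholdK` (beats) | 5 | robust SDs | false-positive rate ≪ 1 per 10⁴ samples |
| `refractoryMs` | 100 | ms | > physiologic minimum beat interval |
| gradient tolerance | 1e-12 | ms/µm | flags stationary surfaces |
| noise `level` | — | robust-SD multiples | scale-free |
| template `amplitude` | 500 | µV | typical cardiomyocyte FP |
| template `width` | 1 | ms | FP downstroke timescale |
| array `pitch` | 200 | µm | standard TiN array geometry |

Coordinates follow the column-row label convention: label *CR* sits at
$x = (C-1)\,\text{pitch}$, $y = (R-1)\,\text{pitch}$, row 1 at the bottom
(y increases upward), so a wave initiated at the bottom-left corner starts
near the origin. Plot axes state this convention.

## Worked example

```{r example}
spec <- shiftT0ToFit(planarWave(speed = 200, direction = 30))
sim <- generateRecording(spec, samplingRate = 20000)
res <- runPipeline(sim$recording, outDir = NULL, quiet = TRUE)
c(meanCV = res$summary$meanCV_mm_s, direction = res$summary$direction_deg,
  nUsed = res$summary$nElectrodesUsed)
```

The recovered mean CV is within 1% of the simulated 200 mm/s and the
direction within 1° of 30°; the residual SD reflects only the one-sample
quantisation of detection. Problem sizes throughout the test suite are a
single wavefront on the 60-electrode array at 10–20 kHz (a few hundred to a
few thousand samples per electrode), 5 replicates per noise level and 100
per dropout count — sizes at which every experiment in the package rebuilds
its data from code in seconds.

## Known limitations

* No spike sorting: the tool targets monolayer wavefronts, not unit
  activity; neural recordings need different machinery.
* No field-potential-duration or repolarisation analysis.
* A single quadratic surface cannot represent colliding wavefronts or
  reentry; inspect the residual diagnostics (`residualDiagnostics()`,
  Shapiro–Wilk on the residuals plus predicted-vs-residual pairs) and the
  isochrone map before trusting a fit.
* 3D signal-progression output is written as numbered PNG frames; movie
  container assembly is left to an external encoder such as ffmpeg.
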