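---
title: "Dissociating rhythmic and arrhythmic sensorimotor ECoG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissociating rhythmic and arrhythmic sensorimotor ECoG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and signal model

`ecogwaves` analyzes multichannel electrocorticography (ECoG) from
sensorimotor cortex recorded during a movement-imagery task, and ships a
synthetic generator with known ground truth so that every analysis stage
can be validated in a closed loop.  The signal model underlying both the
generator and the analysis is

$$ x_c(t) \;=\; b_c(t) \; + \; \sum_{r \in \{\alpha,\beta\}}
   A_{r,c}(t)\, \mathrm{Re}\!\left[ z_r(t)\, e^{i\phi_{r,c}} \right]
   \; + \; h_c(t) \; + \; \varepsilon_c(t), $$

where, for channel $c$:

* $b_c(t)$ is arrhythmic background whose power spectrum is an exact
  power law $P(f) \propto f^{-\chi}$ (synthesized by spectral shaping of
  white noise: Fourier amplitudes multiplied by $f^{-\chi/2}$ with
  random phases), optionally modulated by a slow ($\le$ 0.5 Hz)
  log-normal gain *shared by all channels*;
* $z_r(t)$ is a complex narrowband carrier for rhythm $r$ (Gaussian
  spectral envelope; the power-spectrum FWHM is the stated bandwidth),
  shared across channels, so each rhythm is a single coherent source;
* $\phi_{r,c} = -(2\pi f_r / v_r)\, (\mathbf{p}_c \cdot \hat{u}_r)$ is
  the plane-wave phase offset for propagation direction $\hat u_r$ and
  speed $v_r$ ($\mathbf p_c$ = in-plane electrode position, cm) — an
  *exact* phase plane before any noise;
* $A_{r,c}(t)$ combines the condition-dependent task gain (e.g. 1.3x
  ipsilateral alpha, 0.8x contralateral beta), an optional per-trial
  jitter, and a slow per-channel log-normal envelope (rhythms wax and
  wane locally);
* $h_c(t)$ is a broadband burst component with a shallow $f^{-1/2}$
  spectrum, gated by the contralateral condition — the stand-in for
  movement-related population spiking that raises 60–120 Hz power and
  flattens the 1/f slope;
* $\varepsilon_c(t)$ is white sensor noise (default SD 0.1 of the
  background SD: amplifier noise is small relative to the physiological
  LFP).

Two modeling choices deserve emphasis because earlier drafts got them
wrong in instructive ways.  First, the broadband burst component must
*not* be band-limited to 60–120 Hz: a rectangular spectral plateau is
unphysical and corrupts the IRASA geometric mean from above.  60–120 Hz
is where HFA is *read out*, not where broadband activity lives.
Second, rhythm amplitudes default to spectral peak-to-background ratios
of roughly 3.5–4x — matching what log-log ECoG spectra actually show.
Much stronger rhythms leak displaced spectral mass across the 30–50 Hz
slope band under any resampling-factor set.

## Default parameters (the simulated "participant")

| parameter | default | unit | rationale |
|---|---|---|---|
| array | 8 x 8 grid | — | clinical subdural grid |
| spacing | 10 | mm | clinical standard |
| sampling rate | 512 | Hz | clinical amplifier |
| trials/session | 60 | — | 10-minute session |
| sessions | 2 | — | typical 2 sessions |
| hand alternation | blocks of 10 | trials | task protocol |
| orientations | 15, 24 apart | deg | task protocol |
| 1/f exponent $\chi$ | 1.5 | — | mid-range cortical LFP |
| alpha | 8 Hz, FWHM 4 | Hz | individual alpha band |
| beta | 18 Hz, FWHM 6 | Hz | individual beta band |
| alpha condition gain | contra 1.0 / ipsi 1.3 | — | ipsilateral enhancement |
| beta condition gain | contra 0.8 / ipsi 1.0 | — | contralateral suppression |
| alpha / beta speed | 25 / 60 | cm/s | see "spatial Nyquist" below |
| alpha / beta direction | 90 / 270 | deg | opposite propagation |
| HFA burst gain | 1.5x contralateral | — | movement-related spiking |
| broadband drift SD | 0.6 | log units | excitability state drift |
| local envelope SD | 0.5 | log units | rhythms wax/wane locally |
| behavior | $p = 0.4\sin(\theta \pm 45^\circ) + 0.5$ | — | sine-law grasp choice |

**Spatial Nyquist.** A phase gradient on a grid with spacing $d$ can
only represent wavelengths above $2d$.  At 10 mm spacing the limit is 2
cm, so an 8 Hz rhythm is recoverable only above $v = f\lambda = 16$
cm/s and an 18 Hz rhythm above 36 cm/s.  The patient speeds reported
for these rhythms (5–9 and 11–21 cm/s) are spatially aliased on such an
array for a *single plane wave* of the corresponding frequency;
reproducing those values is out of scope, and the generator's default
speeds are chosen to be resolvable so that recovery is a meaningful
test.  Wave-recovery acceptance uses a 5 Hz rhythm at 15 cm/s
(wavelength 3 cm) for the same reason.

# Spectral decomposition

**Welch spectra.** 1-second Hanning windows, 50% overlap, density
normalization, 1 Hz resolution.

**IRASA.** For each non-integer factor $h$ the signal is Fourier-
resampled to $n h$ and $n/h$ samples and both spectra are computed at
the nominal rate; rhythmic peaks move to $f/h$ and $f h$ while a power
law is a fixed point of the geometric mean
$\sqrt{P_{h}(f)\,P_{1/h}(f)}$.  The median across factors is the
fractal component; `oscillatory = original - fractal` holds exactly
(and is clamped at zero only afterwards).  Two numerical guards:

* the returned frequency range is capped at $f_s / (2 h_{max})$,
  because the expanded signal has no content above that point (the
  "resampling cliff");
* the default factor set is $h \in \{1.10, 1.15, \dots, 1.45\}$ rather
  than the canonical $\{1.1,\dots,1.9\}$.  With $h$ up to 1.9 the
  compressed branch maps an 18 Hz beta bump (FWHM 6) into 30–34 Hz for
  a *majority* of factors, so the median cannot reject the displaced
  mass and the 30–50 Hz slope is biased by more than one log-log unit.
  With $h \le 1.45$ the displaced mass stays below 30 Hz for all but a
  minority of factors.  The canonical set remains available via the
  `factors` argument.

**Band parameterization.** A two- or three-term Gaussian model
$a\,e^{-((f-b)/c)^2}$, FWHM $= 2\sqrt{\ln 2}\,c$, least squares over
1–45 Hz, bounds $b \in [2, 45]$, $a \ge 0$.  The third term is added in
`auto` mode only when a local maximum below 5 Hz exceeds 10% of the
global oscillatory peak.  When the full IRASA spectrum is available the
model is fitted to `original` minus a *robustly fitted power law* of the
fractal component (iterative rejection of upward outliers) rather than
to the raw pointwise residual: the pointwise fractal is inflated on
bump flanks by displaced rhythm mass, which otherwise narrows recovered
FWHMs by ~35%.

**Excitability indices.** The 1/f slope is the straight-line fit of
log10 power against log10 frequency over 30–50 Hz on the fractal
component (steeper = more inhibition); HFA is mean fractal power over
60–120 Hz.  On rhythm-free synthetic spectra the slope fit attains
$R^2 \ge 0.95$.

**Epoch pooling.** Band definition uses task epochs (cylinder on
screen) pooled across trials and sessions, capped at a configurable
duration (default 120 s) per electrode.

# Electrode selection

Stimulation-positive electrodes (motor / somatosensory / both) define
sensorimotor coverage.  Per feature, local maxima are electrodes beyond
the 99% confidence bound of the across-electrode mean
($\mu \pm z_{0.995}\,\mathrm{SEM}$; upper tail for powers and HFA,
lower tail for the slope).  The normal quantile is the default, with a
t-quantile option.  With fewer than three electrodes the selection is
skipped with a warning and all electrodes are retained (mirroring a
participant whose coverage could not be narrowed).  Category tests use
the standard Pearson goodness-of-fit statistic with $k - 1$ degrees of
freedom; inter-set separation is the mean nearest-neighbour distance,
the conservative reading of a single summary figure.

# Band dynamics

Time-frequency maps use 1-s Hanning windows stepped at exactly 50 ms
(window starts are rounded per step so the nominal grid is exact at any
sampling rate).  Inter-session offsets in absolute power are removed
additively per session; percent change is taken against a bootstrapped
pre-stimulus baseline (mean of 1000 resample means over trials,
window −750 to −500 ms).  Time courses of different lengths are mapped
to a common 2-s duration with a cosine-rolloff anti-alias low-pass and
spline interpolation (reflect padding preserves endpoints).

**Time-resolved 1/f correction.** IRASA itself has no temporal
resolution.  The package's stand-in indexes the momentary arrhythmic
level by mean power in the rhythm-free 30–50 Hz band and removes its
within-trial contribution from a band-power time course by per-trial
linear regression.  An earlier design extrapolated a per-window 30–50
Hz log-log fit down into the rhythm band; its prediction noise is
*common to all bands corrected from the same fit* and therefore
manufactures spurious between-band correlation — the regression form
does not.  Without any correction, broadband fluctuations shared across
the spectrum inflate correlations between band envelopes; this is the
package's analog of the original contrast between separated and
unseparated band power.

**Cluster statistics.** Two-sided dependent-samples t-tests at each
time point (cluster-forming p < 0.05), clusters over contiguous
same-sign points, mass = summed t, null distribution of the maximum
mass from sign flips of the paired differences, p with the plus-one
rule.  Units of observation are local-maxima electrodes (all
stimulation-positive electrodes when selection cannot narrow to at
least two).

# Feature similarity

First-order similarity is Pearson correlation within trials: over time
(feature time courses averaged over their own local maxima, −0.75 to 2
s), over space (per-electrode means, 0 to 2 s), and over the flattened
electrode x time pattern.  Undefined correlations from constant
patterns are dropped and counted, not imputed.  Representational
similarity matrices correlate every trial pair's pattern; the
vectorized upper triangle (length $n(n-1)/2$) is compared between
features by Spearman rank correlation.  Group-level inference is a
one-sample t-test plus the JZS Bayes factor BF01 (Cauchy prior scale
$\sqrt{2}/2$ on the standardized effect, marginal likelihood by
numerical integration over the effect size).

A generator subtlety: a latent per-trial "demand" variable that only
scales both rhythms' amplitudes cannot drive second-order similarity,
because Pearson pattern correlations are invariant to trial-wise scale.
The shared demand structure that RSA *can* detect in this world is
condition modulation applied to both bands (the hand condition acting
as the shared latent), which yields second-order rho around 0.1 at 120
trials.  The generator's `demand_coupling` option additionally couples
the rhythms through envelope latency (onset delayed by up to 0.5 s
times a latent uniform variable); its pattern-shape signature is real
but below detection at the default noise levels, and no test claims
otherwise.

# Traveling waves

Band-pass filtering applies the two-pass third-order Butterworth
magnitude response exactly in the Fourier domain (zero phase by
construction, band edges center $\pm$ FWHM/2, reflect padding).
Instantaneous phase is the analytic-signal argument, with
even-reflection edge padding (odd/point-mirror padding injects a DC
step that corrupts the envelope deep into the segment).

Electrode positions are projected onto their first two principal axes.
For (near-)square arrays the principal axes are rotationally
degenerate, so the in-plane rotation is fixed to the lattice
orientation (axial mean of nearest-neighbour displacement directions,
modulo 90 degrees), making the projection deterministic and aligning
the interpolation grid with the electrodes.  Phases are interpolated to
a regular 1-cm grid through their unit vectors (inverse-distance
weights within 1.5 grid steps; electrodes on nodes are used directly),
and gradients are wrapped finite differences along both principal
directions (rad/cm; forward/backward averaged in the interior,
one-sided at edges, masked where support is missing).

* PGD = $\lVert \overline{\nabla\phi} \rVert / \overline{\lVert \nabla\phi \rVert}$.
* Direction = azimuth of $-\overline{\nabla\phi}$ (waves travel from
  phase-leading to phase-lagging sites); verified against the forward
  model.
* Speed = $2\pi f / \mathrm{median}\lVert\nabla\phi\rVert$, the median
  giving robustness to near-zero-gradient sites.
* Null distributions: `time_shuffle` permutes each electrode's phase
  series independently over time.  Permuting whole time frames would
  leave every per-frame PGD (and hence the temporal mean) unchanged,
  so it cannot serve as a null for this statistic; independent
  per-electrode permutation destroys spatial alignment at each instant
  while preserving per-electrode content.  `electrode_shuffle` permutes
  the assignment of series to positions.  p-values use the plus-one
  rule.
* Directional consistency is the across-trial resultant length of local
  gradient directions; the Rayleigh test uses
  $p = \exp(\sqrt{1 + 4n + 4(n^2 - R^2 n^2)} - (1 + 2n))$; direction
  distributions are compared by KL divergence over 36 angular bins
  (natural log, epsilon-regularized) with a label-shuffle null.

# Behavior

$p(\mathrm{overhand}) = a \sin(\theta + \phi_0) + c$ with the period
fixed at 360 degrees (one over/underhand alternation per rotation).
The model is linear in $(\sin\theta, \cos\theta, 1)$, so the fit is a
closed-form global optimum.  Switch points solve the 50% crossing;
demand labels mark orientations within $\pm 24^\circ$ of a switch point
as high, the equivalent range around switch point $+ 90^\circ$ as low.
At 8 trials per orientation the *median* switch-point recovery error
across simulations is ~7 degrees (the mean is ~8.2), which is how the
"within 8 degrees" recovery property is evaluated.

# What a green test does and does not establish

The generator reproduces the statistical structure the analysis
assumes: exact power-law background, Gaussian spectral bumps, exact
plane-wave phase lags, condition-gated amplitude and broadband
modulation, sine-law choices.  It does not simulate epileptiform
activity, volume conduction, cortical folding, non-sinusoidal waveform
shape, or non-planar (spiral/expanding) waves.  Green recovery tests
therefore establish correctness of the estimators under the stated
model, not robustness to every property of patient data; conversely,
none of the study's printed patient values (band centers, PGD, speeds,
KL, variance explained) are reproducible at desk scale, and the test
suite does not pretend otherwise.

# Known limitations

* EDF support is a minimal reader/writer for continuous uniform-rate
  recordings (no annotations, no discontinuous records).
* The 2-vs-3-term model selection keys on a sub-5 Hz local maximum
  exceeding 10% of the oscillatory peak; pathological spectra outside
  the generator's family may need an explicit `model_order`.
* Cluster inference is over time only (band-aggregated series), not
  time x frequency.
* Speed estimates saturate near the spatial Nyquist; on a 10-mm grid
  nothing below $\lambda = 2$ cm is interpretable.
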