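---
title: "Bimodal EEG-fNIRS resting-state analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bimodal EEG-fNIRS resting-state analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nvfusion` implements a resting-state analysis of prefrontal cortex (PFC)
function from simultaneous EEG and functional near-infrared spectroscopy
(fNIRS): synchronization-likelihood (SL) electrode networks on the
electrophysiological side, hemoglobin-concentration connectivity on the
hemodynamic side, permutation-based group inference over both, and a
multimodal source power comodulation (mSPoC) decomposition coupling the two.
Because no patient recordings are available, a synthetic-cohort generator
plants known neurovascular coupling so that every stage has a recoverable
ground truth. This vignette records the models, the parameters that matter,
and the design decisions taken where the methods literature leaves the
choice open.

## The two pipeline arms

**EEG arm.** Raw 64-channel EEG (microvolts; 2048 or 256 Hz) is corrected
for ocular activity by least-squares regression on the EOG channels,
band-pass filtered into six canonical bands — delta (1.5–4 Hz), theta
(4–8), lower alpha (8–10), upper alpha (10–13), beta (14–30), gamma
(30–50) — decimated to 256 Hz, and segmented into contiguous 2-s epochs
after discarding the first 120 s of settling. Epochs in which any channel
exceeds ±150 µV are rejected; the first 10 clean epochs (5120 samples,
20 s) are kept and demeaned per channel. Rejection is decided on the
broadband signal so that all bands share one epoch set.

**fNIRS arm.** Dual-wavelength (690/830 nm) optical density from 14
prefrontal channels at 50 Hz is converted to Δ[HbO]/Δ[Hb] (µM) through the
modified Beer–Lambert law, linearly detrended and band-passed to
0.01–0.1 Hz, motion-corrected by spline interpolation over segments where
the 2-s moving standard deviation exceeds 3× its median, and screened by a
5-SD moving-average rule for low signal-to-noise channels.

## Synchronization likelihood

SL is a generalized-synchronization statistic: both series are
delay-embedded (dimension $m$, lag $\tau$), and for each reference vector
$X_i$ the critical distance $\varepsilon_{x,i}$ is the $p_{ref}$-quantile of
its Euclidean distances to vectors $X_j$ in the comparison window
$w_1 < |i-j| \le w_2$ (the Theiler window $w_1$ excludes
autocorrelation-inflated neighbours). SL is the normalized rate of
*coincident* recurrences,

$$\mathrm{SL} = \frac{1}{M}\sum_i \frac{1}{p_{ref}\,n_i}
  \sum_j \theta(\varepsilon_{x,i} - |X_i - X_j|)\,
         \theta(\varepsilon_{y,i} - |Y_i - Y_j|),$$

which sits at $\approx p_{ref}$ for independent series and at 1 for
identical (or affinely related) ones. Parameters are derived per band:
$\tau = \mathrm{round}(f_s / 3 f_{high})$,
$m = \mathrm{round}(3 f_{high} / f_{low}) + 1$, $w_1 = 2\tau(m-1)$,
$w_2 = w_1 + n_{rec}/p_{ref}$ (defaults $p_{ref} = 0.05$, $n_{rec} = 10$);
all five are overridable.

Numerical choices: Euclidean distances; empirical quantiles with linear
interpolation; recurrence at $d \le \varepsilon$. The optimized core
(C++, per-channel recurrence bit masks shared across the 2016 electrode
pairs) is verified against a naive double-loop implementation to 1e-12.

**Window length vs. epoch length.** For the low bands the derived windows
do not fit inside one 512-sample epoch (lower alpha at 256 Hz gives
$w_2 = 272$, needing $M \ge 546$ embedded vectors). The whole-head analysis
therefore concatenates the 10 kept epochs (5084 embedded vectors) rather
than averaging per-epoch SL; `per_epoch_mean` remains available and errors
cleanly when the window does not fit. Concatenation introduces a small
number of embedding vectors spanning epoch boundaries (36 of 5084 per
joint); their effect is below the estimator's Monte-Carlo noise.

## Hemodynamic connectivity

Pearson correlations between channel time courses of the chosen chromophore
(HbO primarily; Hb computed alongside) give a 14×14 matrix per subject.
Correlations are Fisher z-transformed (atanh) before any averaging or
t-testing; displayed matrices stay in r units. The network threshold
$r_T$ retains the top 5% of connections *of the control-group mean matrix*
and is applied to both groups, so a hypo-connected group can fall below the
nominal edge count. Degree strength $\sigma_i$ is the mean correlation of
channel $i$ with all others on the *unthresholded* matrix; thresholds enter
visualization and edge counts only.

Absolute µM scales depend on the extinction-coefficient table and the
differential pathlength factor (default 6.0 at both wavelengths, 3-cm
source–detector separation); all downstream correlations are invariant to
that scale.

## Group inference

Group differences use Welch's t (the groups have 8 and 11 subjects) with
permutation null distributions built from 1000 random relabelings
preserving group sizes; p-values use the add-one convention
$(1 + \#\{\text{extreme}\})/(1 + B)$, which never returns 0 and differs
from the raw proportion by at most $1/(B+1)$. Subject-level covariates
(age, gender, IQ) can be projected out before permuting.

The cluster-based permutation test controls the family-wise error over the
2016 electrode pairs: edges with uncorrected $p <$ 0.05 are clustered by
the rule *two edges are adjacent iff they share an electrode* (equivalently,
clusters are connected components of the supra-threshold edge subgraph);
cluster mass is $\sum |t|$; the null is the maximum cluster mass per
permutation.

## mSPoC fusion

Feature extraction aligns one EEG channel covariance $C_e$ (band-filtered
2-s epoch) with one fNIRS sample per epoch (window mean of Δ[HbO] after
decimation to 5 Hz). The hemodynamic window sits `lag_epochs` epochs
*after* the EEG epoch; with 2-s epochs, `lag_epochs = 3` matches the
canonical 6-s response peak and is the pipeline default for fusion.

The alternating solver iterates: (i) power series
$\phi(e) = w_{eeg}^\top C_e\, w_{eeg}$, z-scored; (ii)
$w_{fnirs} \propto (\mathrm{Cov}(Y) + \lambda I)^{-1}\mathrm{Cov}(Y, \phi)$
with $\lambda = 10^{-6}\times$ the mean diagonal; (iii) $w_{eeg}$ as the
leading generalized eigenvector of $(\sum_e t(e)\,C_e,\ \bar{C})$ given the
z-scored hemodynamic target $t$. The comodulation $r = \mathrm{cor}(\phi, t)$
is non-decreasing across iterations; the best of `n_restarts` random
initializations is kept, optionally (`polish = TRUE`) refined by direct
ascent on $r$ over the EEG filter (the fNIRS filter has a closed form
given the power series) — the eigenvector step optimizes a covariance
surrogate whose optimum can sit slightly below the correlation optimum.
The refinement runs identically inside permutation refits so the null
stays exchangeable with the observed fit. Patterns are reported as
$a = Cw/\sqrt{w^\top C w}$ — the interpretable forward projections,
invariant to the scale of $w$ — with the largest-|entry| sign fixed
positive.

Significance comes from circularly shifting the epoch pairing and
*refitting the full solver* on each shifted pairing: a fixed-filter null
would ignore the selection optimism of the fit and be anticonservative. The
number of restarts inside null refits must match the observed fit for
exchangeability; both are configurable. Admissible shifts exclude the
smallest rotations (default: less than 20 s, capped at a third of the
record): the hemodynamic series is slow, so a 1-2-epoch shift leaves
genuine coupling largely aligned and would leak it into the null,
costing power without improving validity.

**A degeneracy worth knowing about.** With $n$ aligned windows and $q$
fNIRS channels, the regression step interpolates whenever $q \ge n - 1$:
at the canonical 10-window, 14-channel whole-PFC setting the fitted $r$ is
structurally 1 for any data, and only ROI-level fits (3–4 channels) are
informative. The calibration suites therefore use more windows than
channels; the end-to-end run reports the whole-PFC value as the pipeline
produces it, and this limitation is stated wherever that number appears.

## The synthetic generator

Each subject is built from band-limited Gaussian carriers (spectrally
shaped with the order-4 Butterworth band magnitude) multiplied by positive
log-normal envelopes whose logarithm fluctuates in the infra-slow band
(0.02–0.1 Hz, soft-bounded so power waxes and wanes about seven-fold
without pathological bursts) — resting band power is modulated on exactly
the timescales the hemodynamic analysis band reads out. Electrodes inside
a synchronization community mix a shared community source with weight
$\kappa$ against a private source with weight $1-\kappa$; 1/f background
and white sensor noise are mixed in (`noise_mix`) and channels scaled to
~20 µV RMS. Hemodynamics follow *neural activity*: the instantaneous band
power of the frontal community's shared source (2-s integration),
convolved with a double-gamma HRF (6-s peak, 16-s undershoot, ratio 1/6),
drives Δ[HbO] across a positive spatial pattern with signed gain
`coupling_beta`; pink noise is mixed by `noise_mix`; Δ[Hb] mirrors HbO
with ratio −0.3; optical density is emitted through the forward
Beer–Lambert operator, so the fNIRS arm inverts exactly the operator the
generator used. Optional artifacts: 300-ms biphasic ~100 µV blinks on EOG
and frontal rows, 1-s motion steps on optical-density rows.

Defaults define the study conditions: 64 + 2 + 14 channels, 256 Hz/50 Hz,
660-s records (180-s test preset), cohorts of 11 controls vs 8 patient-like
subjects whose communities are desynchronized (κ × 0.6) and hypo-coupled
(β × 0.5). Where the acquisition regime fixes a value (rates, channel
counts, durations, group sizes, band definitions) it is taken as given;
where it does not, the choice was fixed once against the power targets the
design states (a κ-effect detectable by the mean-SL permutation test at
these group sizes) and not revisited: `sync_kappa = 0.6`, two communities
covering 35% (frontal) and 30% (posterior) of the montage,
`noise_mix = 0.5`, `envelope_band_hz = c(0.02, 0.1)` (a faster or slower
log-envelope would put the planted power fluctuations outside the
0.01–0.1 Hz hemodynamic analysis band, where the high-pass edge or the
HRF low-pass removes them from one modality but not the other, and no
finite-sample method could couple the two).

What the generator does *not* emulate: volume conduction and a realistic
leadfield, physiological pulse/respiration bands in the optics, scalp
coupling losses, or any nonstationarity beyond the envelopes. Passing
tests therefore demonstrate correctness of the estimators under a
controlled neurovascular model, not clinical validity on human data.

## Numerical choices

* **Filters.** All zero-phase filtering designs Butterworth poles in
  zero-pole form and applies cascaded biquads forward–backward (odd
  reflection padding, steady-state initial conditions). Transfer-function
  (b,a) polynomials become numerically unstable for narrow bands at
  2048 Hz, and a high-pass/low-pass cascade loses ~50% gain at the centre
  of 8–10 Hz; both alternatives were rejected after measurement. Band-pass
  order 4 (EEG), 3 (fNIRS); anti-alias low-pass order 8 at 0.8× the target
  Nyquist before decimation; band filtering happens at the native rate
  before decimation.
* **Detrend before high-pass.** The printed stage order (band-pass, then
  detrend) is available via `strict_order = TRUE`; the default folds the
  linear detrend in front of the 0.01-Hz high-pass edge, which is
  numerically safer on finite records. On records shorter than three
  high-pass time constants (300 s) the edge is auto-relaxed with a warning.
* **Spline motion correction.** Artifact threshold 3× median moving SD,
  merge gap 0.5 s, csaps-style smoothing 0.99 (mapped onto
  `stats::smooth.spline`), re-levelling against 1-s flanks: conventional
  values from the motion-artifact literature, all configurable.
* **Degenerate inputs.** Constant series are an error for SL (undefined
  distances) and auto-excluded for correlation; |r| = 1 is clipped to
  1−1e-7 before atanh with a warning; ties at the network threshold are
  all retained (the edge count may exceed the nominal k).

## Problem sizes used by the test and acceptance suites

The statistical calibrations simulate at reduced size, chosen once as a
simulation-design decision: null and power cohorts use 8–12 electrodes,
150–180-s records and 5–10 kept epochs (SL windows derived with
`n_rec = 5`); the null cluster/edge calibration draws 100 cohorts from a
pool of 200 independently simulated null subjects; mSPoC calibrations use
6 electrodes × 4 channels with refitted 49-shift nulls — null calibration
on 180-s records (75 aligned windows; windows > channels so the statistic
is non-degenerate, and enough of them that the circular-wrap discontinuity
is a small perturbation), detection power and pattern recovery on
420–660-s records (145–260 windows), since the slow hemodynamics carry
only a handful of effective degrees of freedom per minute. The
end-to-end acceptance run keeps the full 64 + 14-channel montage, 180-s
records, 11 vs 8 subjects, all six bands, and 1000-permutation tests.

## Known limitations

* SL concatenation mixes epochs; with heavy rejection the concatenated
  series is not strictly stationary across joints.
* The mSPoC temporal model has no HRF deconvolution on the band-power
  series; couplings are detected through correlation at a fixed epoch lag.
* The whole-PFC fusion at the canonical 10-window setting is degenerate
  (r = 1) as described above.
* EDF support covers the common single-rate 16-bit layout; BDF and mixed
  per-channel rates are rejected, not converted.
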