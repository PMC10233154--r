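---
title: "Assessing training-free SSVEP detection: models, simulator, and evaluation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing training-free SSVEP detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvepbench)
```

## The problem

A steady-state visually evoked potential (SSVEP) is an oscillatory occipital
response locked to the frequency of a flickering stimulus and its harmonics.
Brain--computer interfaces exploit it by showing several targets flickering
at distinct frequencies and asking which one the user attends, decided from
a short segment of multi-channel EEG. This package implements the three
standard *training-free* decoders --- canonical correlation analysis (CCA),
filter-bank CCA (FBCCA) and minimum energy combination (MEC) --- together
with the spectral characterization (segment-averaged PSD, wide-band SNR,
stimulation-versus-baseline contrast maps) and a pseudo-online evaluation
layer (sliding windows, a consecutive-agreement decision rule, and the
detection-accuracy / detection-time / information-transfer-rate metrics).
Every stage is testable end to end on a bundled synthetic session generator
that reproduces the usual experimental layout: four visual paradigms (On-Off
or Checkerboard pattern, Rectangular or Sinusoidal luminance modulation), 40
trials per run, 15-s trials (Fixation 2 s, Target 2 s, Preparation 1 s,
Stimulation 5 s, Rest 5 s), five targets at 8.5714, 10.9091, 15, 20 and
24 Hz (integer divisors of a 240 Hz display refresh), eight
parieto-occipital/occipital channels at 256 Hz.

## The detectors

All three decoders share one contract: given a window $X \in
\mathbb{R}^{N_e \times N_t}$ and a candidate frequency $f_i$, produce a
score; the candidate with the largest score is the decision (exact ties go
to the lowest frequency).

**Reference templates.** Each candidate is represented by the harmonic
matrix $Y_{f_i} \in \mathbb{R}^{2N_h \times N_t}$ whose rows alternate
$\sin(2\pi k f_i t)$ and $\cos(2\pi k f_i t)$ for $k = 1..N_h$, $t = n/f_s$.
The default $N_h = 4$; harmonics at or above Nyquist are dropped, never
aliased.

**CCA** scores a candidate by the largest canonical correlation $\rho$
between row-centered $X$ and $Y_{f_i}$, obtained from the generalized
eigenvalue problem on $C_{pp}^{-1} C_{pq} C_{qq}^{-1} C_{qp}$. A relative
ridge ($10^{-9} \cdot \mathrm{tr}/p$) stabilizes the auto-covariance
inverses; the implementation is verified against an independent QR/SVD
construction of the canonical correlations to $10^{-8}$.

**FBCCA** first decomposes $X$ into $SB = 5$ sub-bands with Chebyshev
type-I band-pass filters (6--90, 9--90, 13--90, 18--90, 22--90 Hz), applies
CCA between each sub-band signal and the *unfiltered* template, and
combines $\tilde\rho_{f_i} = \sum_n w(n)\,\rho_n^2$ with $w(n) = n^{-a} +
b$, $a = 1.25$, $b = 0.25$. The weight function rewards the lower sub-bands
(which retain the fundamental) while still counting the harmonic-only
bands; this is why responses with genuine harmonic structure outscore
fundamental-only responses of equal total power.

**MEC** fits the harmonic model by least squares, $G = X Y^\top (Y
Y^\top)^{-1}$, and treats the residual $\eta = X - G Y$ as nuisance
activity. Spatial filters are the eigenvectors of $M = \eta\eta^\top$ with
the *smallest* eigenvalues, scaled $v_i/\sqrt{\lambda_i}$ so each filtered
residual carries unit energy; the number retained, $N_m$, is the smallest
count of ascending eigenvalues whose cumulative sum exceeds 10% of the
total (at least 1). The candidate's score is the average squared projection
of the spatially filtered channels onto the template rows,
$p_{f_i} = \frac{1}{N_m N_h}\sum_{i}\sum_{j} (y_j^{\phantom{\top}}
X^\top w_i)^2$.

### Numerical choices

* Chebyshev-I order 4 with **0.2 dB** pass-band ripple, applied zero-phase
  (forward--backward). Zero-phase application squares the magnitude
  response, so a 0.5 dB design would dip to $-1$ dB (an 11% RMS loss) in
  the pass band; 0.2 dB keeps the pass band within 5% while still
  attenuating a 4 Hz tone by more than 15 dB in the first band. Stability
  (all poles strictly inside the unit circle) is asserted at design time.
* The MEC power uses squared projections. The raw-product form cancels for
  arbitrary phase relationships between signal and template and is retained
  only as `literal = TRUE` for comparison. Eigenvalue scaling uses
  $v_i/\sqrt{\lambda_i}$ (unit-variance filtered noise) with a floor of
  $10^{-12}\lambda_{\max}$.
* All detectors center channels internally; CCA and FBCCA scores are also
  invariant to global amplitude scaling. A constant (all-zero) window is a
  validation error, not a silent answer.

## The synthetic session generator

The generator's signal model mirrors the decomposition the detectors
assume: channel $e$ during stimulation is

$$x_e(t) = \underbrace{\textstyle\sum_{h=1}^{N_h} A_{e,h}\, g_{\mathrm{par}}
\sin(2\pi h f t + \phi_{e,h})}_{\text{evoked}} + \eta_e(t),$$

where $\eta$ is pink ($1/f^\gamma$, default $\gamma = 1$, broadband RMS
10 µV) noise plus a band-limited 8--13 Hz alpha component (RMS 2 µV),
both per channel and zero-mean. Defaults that the experiment layout fixes
(sampling rate, channels, trial phases, trial counts, frequencies) follow
the standard protocol above. Defaults the protocol does not fix were chosen
once on field-typical grounds:

* **Harmonic amplitudes** decay as $1/h$ with occipital channels (O1, Oz,
  O2) weighted above the parieto-occipital ring --- the usual scalp
  topography of the response. Fully exposed as an $N_e \times N_h$ matrix.
* **Paradigm gains** are OOR = OOS = 1 and CBR = CBS = 1/3: checkerboard
  responses are substantially weaker than On-Off responses at the same
  response frequency. Both checkerboard paradigms use the *same* nominal
  frequencies as On-Off, because pattern-reversal stimuli evoke activity at
  the alternation rate --- the listed frequencies are already the response
  frequencies; only the gain differs.
* **Background levels** (10 µV broadband, 2 µV alpha) are typical
  eyes-open occipital magnitudes. The alpha band deliberately overlaps the
  8.57 and 10.91 Hz targets, reproducing the real-world hazard that
  ongoing alpha masquerades as low-frequency SSVEP.
* **Seeding**: one master seed; per-trial sub-seeds are derived by a
  deterministic integer recurrence over (paradigm, trial) indices, so
  identical configurations give byte-identical sessions and any single
  trial is reproducible in isolation.

### SNR calibration

`target_snr_db` asks the generator to scale the evoked component so the
stimulation segments attain a given *measured* wide-band SNR,

$$\mathrm{SNR} = 10\log_{10}\frac{\sum_k P(k f_i)}{\sum_f P(f) - \sum_k
P(k f_i)},$$

evaluated with the package's own estimator (2-s Hanning segments,
nearest-bin harmonic lookup, denominator over the full one-sided grid). Two
estimator properties make a naive power-ratio calibration wrong, and the
generator accounts for both:

1. A Hanning-tapered tone on a bin center leaves only 2/3 of its power in
   that bin; the leaked third lands in neighboring bins, i.e. in the
   denominator. Off-center tones (8.5714 Hz on a 0.5 Hz grid) capture
   slightly less. The generator computes each harmonic's exact bin-capture
   fraction and solves for the amplitude scale by root finding, per trial,
   against the realized background power in the stimulation window.
2. Because leakage scales with the signal, the estimator *saturates* near
   $10\log_{10}(2) \approx +3$ dB for on-bin tones. Targets above the
   ceiling fall back to plain power-ratio scaling, so the evoked amplitude
   remains monotone in the requested target even where the measured value
   cannot follow.

The calibration applies to the unit-gain (On-Off) response; the paradigm
gain multiplies on top, so checkerboard runs measure lower by roughly
$20\log_{10}(3) \approx 9.5$ dB (compressed somewhat by the saturation and
by alpha power under the low-frequency harmonic bins).

## Spectral analysis

`compute_psd()` averages one-sided periodograms over non-overlapping 2-s
Hanning-tapered segments (trailing remainder discarded; a 5-s epoch yields
2 segments), normalized so the density integrates to the variance
(Parseval holds to within Monte-Carlo error). At 256 Hz the native grid
step is exactly 0.5 Hz; the reporting grid is 2--50 Hz. That grid has **97**
points --- protocol descriptions sometimes quote 96; the package reports its
actual grid size and corrects for 8 × 97 tests. `condition_contrast()`
compares per-epoch PSD values cell-by-cell with the Wilcoxon rank-sum test
(the unpaired form, as named; a signed-rank flag exists) at α = 0.01 with
Bonferroni correction. With the normal-approximation p-values, roughly 20
epochs per condition are needed before complete separation can clear the
corrected threshold --- fewer epochs make the map structurally unable to
reject, which the power tests respect.

## Pseudo-online evaluation

Detection epochs span 6 s, from 1 s before stimulation onset to its end.
Windows of `T_win` = 1 s slide in `T_shift` = 0.05 s steps (101 windows);
every window is scored, but only windows ending strictly after onset feed
the agreement counter, since detection time must measure post-onset
evidence. The decision is the first frequency to win three consecutive
counted windows; DT is the end time of the third. If no triple ever agrees
the trace falls back to the last window's decision with DT = 5 s, is marked
undetected-by-rule, and counts as incorrect (a flag can credit a correct
last window instead). ITR uses $s \,[\log_2 N + DA \log_2 DA +
(1-DA)\log_2\frac{1-DA}{N-1}]$ with $s = 60/DT$ selections per minute,
the $0\log 0 = 0$ limit at $DA = 1$, and a clamp to 0 at or below the
$1/N$ chance level. Detection-time averages are reported both over all
trials (fallback contributing 5 s) and over rule-detected trials only,
since protocols rarely state which convention their tables use.

**A structural property worth knowing.** Consecutive 1-s windows shifted by
0.05 s share 95% of their samples, so per-window decisions are strongly
correlated. On a stationary background --- and the synthetic background is
stationary within a trial, with a coherent alpha component that makes one
low-frequency candidate decisively "best" on pure noise --- the first three
counted windows (ending 0.05--0.15 s after onset, hence ≥ 85% pre-onset
data) almost always already agree, and the rule fires at DT ≈ 0.15--0.25 s
with whatever the noise favors. Sliding-window accuracy then reflects the
collision between that premature decision and the early-window strength of
the true response, and saturates well below 1 even for strong responses.
Real recordings show the same phenomenology in weak-response conditions
(checkerboard cells with very short mean DT at unchanged accuracy); their
greater nonstationarity is what keeps noise decisions flickering --- and DT
nearer 1 s --- elsewhere. This is why passing tests on the synthetic
sessions demonstrate the *mechanics* of the rule (window counts, agreement
logic, fallback) and trial-level detector recovery, but deliberately do not
assert sliding-window accuracies or detection times as if they generalized
to real data.

Trial-level accuracy (one decision per 5-s stimulation epoch) is the
detector-facing figure of merit: at a calibrated 0 dB wide-band SNR all
three detectors recover 40/40 trials; accuracy degrades through a sharp
psychometric transition around −25 to −30 dB (5-s windows), and in that
regime reproduces the canonical ordering FBCCA > CCA > MEC. The paradigm
comparison in the acceptance suite runs at −25 dB for the On-Off condition
--- chosen from that psychometric scan so the On-Off runs sit on the upper
shoulder while the 1/3-gain checkerboard runs (≈ −34.5 dB) sit near
chance, letting the qualitative On-Off > checkerboard pattern and its
Kruskal--Wallis signature (pattern-vs-pattern pairs significant,
within-pattern pairs not) express themselves.

## Statistical comparisons

`compare_conditions()` runs the Kruskal--Wallis omnibus across condition
groups and follows up with pairwise rank-sum tests under Holm family-wise
correction, reporting 0.001/0.01/0.05 significance tiers. Null-calibration
tests assert rejection counts inside exact binomial 95% acceptance regions
for the nominal rates rather than point equality.

## Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` run entirely on generated data:
40-trial single-paradigm runs for detector recovery, 20 trials per point on
the SNR grid {−20, −10, 0, +10} dB, 200 trials for chance-level baselines,
50 simulated maps (20 + 20 epochs each) for the contrast-map null, 200
simulations for the omnibus null, and a 2-trials-per-frequency,
two-paradigm session for the sliding-window assessment. These sizes were
chosen so every stochastic assertion has a calibrated acceptance region
while the whole suite completes in a few minutes on one core.

## Known limitations

* The background model is stationary within a trial: no blinks, eye
  movements, electrode drift, or amplitude nonstationarity. Consequences
  for the sliding rule are discussed above; SNR-level conclusions transfer
  more directly than detection-time conclusions.
* Response amplitude is homogeneous across simulated trials apart from the
  per-trial noise realization; real inter-subject variability is exposed
  through the amplitude matrix but has no grounded default.
* The recording container is a plain-text matrix + JSON sidecar pair;
  adapters for binary acquisition formats plug in at the documented
  `format` field of the sidecar.
* Luminance waveforms are not modeled: rectangular versus sinusoidal
  modulation enters only through which paradigm label (and gain) a run
  carries.
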