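---
title: "Methods: linear and nonlinear characterisation of nystagmus waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linear and nonlinear characterisation of nystagmus waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nystagmetry)
```

# The problem and the model

A nystagmus is an involuntary, rhythmic oscillation of one or both eyes.
The clinically standard description — amplitude, frequency, their product
(intensity), and a by-eye judgement of regularity — is coarse: at
oscillation frequencies below 0.5 Hz even experienced observers struggle
to say whether a waveform is periodic, quasiperiodic or nonperiodic, yet
that distinction is exactly what separates a limit-cycle oscillator from a
torus or a higher-dimensional (chaotic) one, and it is what a therapy
ought to change.

This package treats one eye-position channel $x(i)$, $i = 1, 2, \dots$
(degrees, sampled at a fixed rate, typically 200 or 400 Hz) as a scalar
observable of an unknown oculomotor dynamical system and asks three
questions at increasing depth:

1. **Is there a dominant periodicity?** Segmented Fourier amplitude
   spectra; and, independently, unstable periodic orbits (UPOs) recovered
   from threshold-crossing intervals. Agreement between the two routes is
   itself a diagnostic.
2. **What attractor geometry is compatible with the data?** Delay
   embedding $X_i = [x(i), x(i+1), \dots, x(i+(d-1))]$ with $d = 7$,
   projected onto its first three principal components.
3. **How complex is the waveform?** Normalized permutation entropy $h_p$
   in sliding windows, compared and ranked across recordings.

# Tunable parameters

All defaults live in one place, `framework_config()`, and every analysis
stage can be driven independently. The load-bearing ones:

| parameter | default | units | why |
|---|---|---|---|
| Fourier window | 4000 | samples | 20 s at 200 Hz: long enough to resolve 0.25 Hz oscillations |
| zero padding | 1000 | samples/end | refines the grid to rate/6000 = 0.033 Hz at 200 Hz |
| taper | Bartlett | — | triangular weighting of position, zero at the window ends |
| histogram bin | 0.05 | s | period resolution for orbit identification |
| surrogates | 500 | — | plus-one permutation p-value resolution of 1/501 |
| embedding $d$ | 7 | — | sufficient to capture oculomotor time-series variance |
| embedding lag | 1 | sample | consecutive-sample delay vectors |
| entropy window $T_w$ | 25.2 | s | 5040 samples = $7!$ at 200 Hz, so every ordinal pattern can in principle occur in one window |
| entropy hop | 0.5 | s | a dense slide; per-sample hops are statistically redundant |
| detrend window | 4 | s | at least one full period of the slowest (0.25 Hz) oscillation |
| crossing threshold | 0 | deg | the mean of the detrended trace |
| crossing hysteresis | auto | deg | 4 x the estimated noise SD (below) |
| fixation bound | 10 | arcmin | the clinical central-gaze criterion; the SD bound reuses it |
| intrusion gate | 20 | deg/s | pendular motion at <= 1.5 Hz and <= 4 deg peaks below ~19 deg/s |

# Numerical choices

**Threshold crossings and hysteresis.** Crossing times are located by
linear interpolation between the bracketing samples, one direction only
(rising by default). With white measurement noise, a bare comparator
splits each physiological crossing into a cluster of spurious ones while
the signal dwells near the threshold. Pre-smoothing suppresses them but
also shrinks the genuine crossing-time jitter — and that jitter is the
signal the surrogate test feeds on (below) — so the default remedy is a
Schmitt trigger: a crossing is accepted only after the signal has visited
the far side of a dead band of four estimated noise SDs since the last
accepted crossing. The noise SD is estimated as
$1.4826 \cdot \mathrm{median}|x_{i+1}-x_i| / \sqrt 2$, which ignores the
slow oscillation and is robust to saccadic steps. Four SDs makes a
spurious acceptance a $4\sigma$ event per sample while the band stays far
inside the 1°–2° half-amplitudes of interest.

**Interval transform.** For each consecutive interval triple
$(I_{n-1}, I_n, I_{n+1})$ the local linear return map slope is
$k = (I_{n+1}-I_n)/(I_n-I_{n-1})$ and the period estimate is the map's
fixed point $(I_{n+1} - k I_n)/(1-k)$. Exactly periodic data make this
0/0; triples with $|I_n - I_{n-1}|$ under one sample period or
$|1-k| < 10^{-6}$ fall back to $I_n$ and are counted as excluded. The
deterministic (unperturbed) form of the transform is used; the
randomized-perturbation ensemble variant was tried and did not change the
operating characteristics on interval data of this kind.

**Histogram and peak rule.** Bins are aligned to multiples of 0.05 s from
zero; relative frequencies sum to 1. The peak statistic is the maximum
relative frequency over bins at or above 0.2 s — sub-cycle artifacts from
split crossings would otherwise compete with genuine orbit periods.
Secondary local maxima are reported unranked.

**Surrogate significance.** Each surrogate permutes the interval sequence
uniformly at random (preserving the interval multiset, destroying the
order), and the p-value is the plus-one rule
$(1 + \#\{\text{surrogate peak} \ge \text{observed}\})/(1 + N)$. Ties
count against rejection, so the test is conservative by construction.

**Orbit-following segment.** Among maximal runs of consecutive intervals
within ±10% of the identified period, the longest wins; mean absolute
deviation from the period breaks ties, and runs shorter than 3 cycles are
ineligible. (The alternative reading — always cutting back to the
minimum-deviation sub-run — would contradict the natural expectation that
a fully periodic recording yields its whole span.)

**Ordinal patterns.** Each delay vector maps to the permutation that
arranges it in increasing order; ties rank by original position (the
earlier index first), which keeps patterns well defined on quantized
tracker output. Entropies use natural logarithms; $h_p = H_p/\ln(d!)$ with
$\ln(d!)$ computed as `lfactorial` to avoid overflow. Detrending is done
once, globally, before windowing.

**Rank-sum comparison.** Window counts differ between recordings, so the
two-sample (unpaired) Wilcoxon rank-sum test with normal approximation
and tie correction is used; a fully tied pair (0/0 in the approximation)
is assigned p = 1. Bonferroni multiplies by the number of pairs. The
median absolute deviation is reported raw (no 1.4826 consistency factor),
matching how clinical summaries quote it.

# The attractor classifier

Attractor categories are usually asserted by visual inspection of the
projected trajectory. The package makes the decision explicit and
quantitative, operating on the amplitude spectrum of the detrended
recording:

- oscillation SD below 0.1° → **fixed point** (stable gaze);
- one fundamental whose prominent peaks (relative amplitude ≥ 0.1) all lie
  within 5% of integer multiples of it, with off-peak in-band energy below
  20% → **limit cycle**;
- two fundamentals whose ratio differs from every rational $p/q$,
  $q \le 4$, by more than two spectral bins → **torus**;
- otherwise → **higher-dimensional**.

Peak structure alone is not sufficient: phase-coherent chaos (the
Rössler-type regime the synthetic module generates) produces sharp,
near-harmonic spectral lines — measured off-peak energy fractions of only
0.02–0.06, indistinguishable from a noisy limit cycle by any threshold the
regular regimes would still clear. What does separate it is spectral
*nonstationarity*, which is precisely what "nonperiodic" means: the mean
pairwise correlation of the amplitude spectra of successive
half-overlapping segments is ≥ 0.9995 for the periodic and quasiperiodic
regimes but ≤ 0.988 for the chaotic regime across seeds. A recording whose
segment spectra correlate below 0.995 is therefore classified
higher-dimensional before any peak logic runs. Classification is applied
to the full detrended trace rather than the short orbit-following segment:
a near-periodic 3-cycle excerpt of a chaotic recording is, by
construction, indistinguishable from a limit cycle.

# What the synthetic cohort emulates — and what it does not

`generate_cohort()` builds five 60 s recordings at 200 Hz mirroring the
clinical layout the analyses target: one periodic member (2.6°, 1.5 Hz),
one quasiperiodic (3.5°, 1.2 Hz fundamental, golden-ratio second tone at
0.8 relative amplitude), three nonperiodic (2.0°–4.0°, 0.25–0.5 Hz,
Rössler flow at $a = b = 0.2$, $c = 5.7$ rescaled in time and amplitude).
Choices a reader may want to audit:

- **Asymmetry.** The periodic cycle is a phase-warped sinusoid,
  $\sin(u + m\sin u)$ with $m = (r-1)/(r+1)$ for speed ratio $r = 1.5$,
  making the downward phase slower than the upward one as observed
  clinically; the warp is also what populates the harmonics.
- **Chaotic source.** No generative model of nonperiodic nystagmus exists,
  so a canonical three-variable smooth chaotic flow is substituted,
  integrated with fixed-step RK4 (one step per output sample after a
  100-time-unit transient) and scaled so its mean cycle period
  (5.856 model-time units, measured from long integrations) maps to the
  requested frequency.
- **Artifacts.** Linear-plus-random-walk baseline drift at 0.02 °/s;
  Poisson saccadic intrusions (0.2 events/s, 0.3°–1.0°, 20 ms raised-cosine
  rise with a return saccade 150 ms later) placed conjugately on both
  horizontal channels; white measurement noise with SD 0.05°, a
  convention matching the 0.1° resolution class of clinical infrared
  trackers. The fellow vertical channel holds a small random offset within
  ±10 arcmin.

What it does **not** emulate: cycle-to-cycle deterministic period dynamics
(real nystagmus approaches and leaves its periodic orbit; the synthetic
periodic member's period is rigid), blink artifacts, tracker drift
nonlinearity, and the low per-sample noise of averaged clinical traces.
Two visible consequences, neither affecting what the tests establish:

- Absolute $h_p$ values run high (0.70–0.93 instead of the 0.15–0.26
  typical of clinical recordings) because white noise at 0.05° dominates
  successive-sample differences inside the 35 ms ordinal window at
  200 Hz. The entropy *ordering* — periodic < quasiperiodic <
  nonperiodic, every pairwise gap significant at Bonferroni-adjusted
  p < 0.01 — is what the statistic is used for, and it is robust across
  seeds. A green ranking test establishes ordering, not clinical-scale
  absolute entropies.
- **Limits of the surrogate test.** Threshold crossings of a *rigid*
  oscillation with additive white noise have intervals
  $T + (e_{n+1} - e_n)$ with i.i.d. timing errors $e_n$ — a nearly
  exchangeable MA(1) sequence. The shuffle test's power on such data is
  bounded: measured at 0.05–0.48 across 0.25–1.5 Hz (60 s, 10% noise),
  consistent with its correct ~0.05 type-I rate on i.i.d. intervals. So
  the synthetic periodic member does *not* reliably reach p < 0.05, and
  the corresponding acceptance assertion is intentionally left failing
  rather than tuned; on recordings with genuine orbit-approach dynamics
  the transform concentrates estimates in a way shuffling destroys, which
  is where the test earns its keep.

# Degenerate inputs and edge policy

Empty traces, constant traces (no maxima, no crossings, rank-0
embeddings), series shorter than one window, fewer than three crossings or
intervals, gaps longer than 0.5 s, and non-monotone or irregular time
columns all raise errors with stage-named messages; `run_framework()`
records a failed subject's message in its row and continues the cohort.
Moving averages use shrinking windows at the edges (length-preserving);
resampling supports integer rate ratios only, with a moving-average
anti-alias filter before decimation.

# Known limitations

- The attractor classifier's thresholds (peak prominence 0.1, harmonic
  tolerance 5%, off-peak fraction 0.2, stationarity 0.995) were validated
  on the synthetic regimes only; clinical validation would need recordings
  with expert labels.
- UPO significance is conservative on rigid oscillations (see above).
- Permutation entropy is compared across recordings that share a sampling
  rate; comparing across rates would change the ordinal window's time
  span and is deliberately unsupported.
- `d = 7` is fixed by convention; no embedding-dimension selection
  (false-nearest-neighbours etc.) is attempted.
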