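# nystagmetry

Quantitative characterisation of nystagmus waveforms — the involuntary,
rhythmic ocular oscillations seen in clinic — from multi-channel
eye-position recordings. The package is aimed at oculomotor researchers and
clinicians who want to go beyond the standard chart-reading assessment and
ask, objectively: *is this oscillation periodic, quasiperiodic or
nonperiodic, and how complex is it?*

It combines a linear and a nonlinear systems view of the same recording:

- **Standard clinical assessment** — per-channel position means and SDs,
  per-cycle amplitude A (peak-to-peak, degrees) and frequency f (Hz),
  intensity A x f (deg·Hz), the ±10 arcmin fixation-stability criterion,
  and velocity-gated detection of saccadic intrusions (0.3°–1.0° steps).
- **Segmented Fourier analysis** — amplitude spectra of successive
  4000-sample windows, triangular (Bartlett) tapered and zero-padded by
  1000 samples per end, giving a 0.033 Hz grid at 200 Hz; dominant
  frequency per segment.
- **Unstable periodic orbit (UPO) analysis** — threshold-crossing
  intervals I_n transformed through the fixed point of the local linear
  return map I_{n+1} = k I_n + b (estimate = (I_{n+1} − k I_n)/(1 − k)),
  binned at 0.05 s; the histogram peak identifies the orbit period and is
  tested against shuffled-interval surrogates with a plus-one permutation
  p-value.
- **Attractor reconstruction** — delay embedding X_i = [x(i), …, x(i+d−1)]
  at d = 7, principal-component projection to 3-D, and a quantitative
  classifier (fixed point / limit cycle / torus / higher-dimensional) based
  on spectral peak structure, harmonic and incommensurability tests, and
  spectral stationarity across segments.
- **Permutation entropy** — ordinal patterns of the d = 7 delay vectors,
  H_p = −Σ P_j ln P_j and h_p = H_p / ln(d!) ∈ [0, 1], computed in
  overlapping 25.2 s windows (5040 samples = 7! at 200 Hz) after
  moving-average detrending; recordings are compared by pairwise Wilcoxon
  rank-sum tests with Bonferroni correction and ranked by median h_p
  (increasing waveform complexity).

A seeded synthetic-cohort generator (asymmetric pendular, golden-ratio
two-tone, and Rössler-flow regimes, plus baseline drift, saccadic
intrusions and measurement noise) stands in for subject recordings, so the
whole framework is testable end to end.

## Worked example

```r
library(nystagmetry)
cohort <- generate_cohort(seed = 1)   # 5 members mirroring the clinical layout
report <- run_framework(cohort, framework_config(seed = 1))
print(report)
```

```
<framework_report>
 subject channel mean_amplitude mean_frequency intensity fourier_hz upo_hz
      S1     R_V         3.3434         0.5023    1.6792     0.5000 0.4706
      S2     L_V         2.7469         1.5016    4.1249     1.5000 1.4815
      S3     L_V         2.0086         0.6690    1.3438     0.5000 0.4706
      S4     R_V         1.8369         0.4867    0.8940     0.2333 0.2484
      S5     R_V         2.4896         2.0052    4.9921     1.2000 1.2903
  upo_p          attractor median_h_p mad_h_p note
 0.3713 higher_dimensional     0.8983  0.0015
 0.9980        limit_cycle     0.6999  0.0016
 0.8802 higher_dimensional     0.9216  0.0012
 0.0060 higher_dimensional     0.9327  0.0012
 0.5329              torus     0.7501  0.0022
<entropy_comparison>
 series median_h_p     mad_h_p n_windows
     S1  0.8982569 0.001480329        70
     S2  0.6998898 0.001570708        70
     S3  0.9215826 0.001221787        70
     S4  0.9327317 0.001188436        70
     S5  0.7500647 0.002200537        70
ranking (increasing complexity): S2 -> S5 -> S1 -> S3 -> S4
10/10 pairs significant at adjusted p < 0.01
```

Reading the table: each row is one recording. `mean_amplitude` x
`mean_frequency` = `intensity` is the clinical oscillation strength;
`fourier_hz` and `upo_hz` are the dominant periodicities found by the
linear and nonlinear routes (they agree within 0.1 Hz for the periodic
member S2, as they should); `attractor` is the reconstructed geometry —
the periodic member is a limit cycle, the two-tone member a torus, the
three chaotic members higher-dimensional; `median_h_p` is the normalized
permutation entropy, and the ranking orders the members by increasing
waveform complexity: periodic < quasiperiodic < the three nonperiodic
members, with all 10 pairwise gaps significant at Bonferroni-adjusted
p < 0.01. (Absolute h_p values are higher than in typical clinical
recordings because the generator's white measurement noise dominates the
35 ms ordinal windows; the ordering, which is what the statistic is for,
is unaffected — see the methods vignette.)

## Command line

```sh
Rscript inst/cli/nystagmetry simulate --out cohort --seed 1
Rscript inst/cli/nystagmetry analyse --out report --seed 1 cohort/S1.csv cohort/S2.csv
Rscript inst/cli/nystagmetry report --in report
```

`analyse` accepts a flat `key = value` config file (`--config`) overriding
any `framework_config()` default.

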