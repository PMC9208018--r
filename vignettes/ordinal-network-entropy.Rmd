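---
title: "Ordinal-pattern entropy and network coupling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordinal-pattern entropy and network coupling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordinet)
```

## The measures

`ordinet` analyses multichannel neural time series through ordinal patterns.
A window of `n` samples spaced `tau` samples apart is reduced to the
permutation of its amplitude ranks: the highest amplitude gets rank 1, the
lowest rank `n`. Equal amplitudes — measure-zero in source-reconstructed
MEG/EEG but common in synthetic or quantized data — are ranked by temporal
order, the earlier sample receiving the better rank, which keeps
symbolization deterministic. Each rank vector is encoded as its 0-based
lexicographic index among the `n!` permutations. Note that the
highest-amplitude-first convention is the reverse of argsort-based
conventions used by several permutation-entropy libraries: entropy values
agree, individual symbol codes do not.

*Permutation entropy* (PE) is the Shannon entropy (natural log) of the
symbol distribution, normalized by `log(n!)`, so PE lies in [0, 1]: 0 for a
strictly monotone ramp, approaching 1 for white noise.

*Joint permutation entropy* (JPE) extends this to channel pairs: the joint
distribution of simultaneous symbol pairs has `n!·n!` bins, and its entropy
measures how unconstrained the two channels are jointly. Because
conventional connectivity grows with coupling while a joint entropy shrinks,
the package reports the inverted value `JPE_inv = 1 − JPE`.

### Volume-conduction correction

Instantaneous linear mixing (volume conduction / field spread) makes a
single source appear in several reconstructed channels at lag zero, with
either equal or opposite sign. In symbol space this shows up precisely as
*identical* or *mirrored* (rank-complemented, `r -> n+1-r`) pattern pairs.
The correction excludes those `2·n!` cells from the joint matrix before the
entropy sum. The exclusion set is computed from the actual
identical-union-mirrored set rather than hard-coding its size; for every
`n ≥ 2` no pattern equals its own mirror, so the set has exactly `2·n!`
cells, but the code does not rely on that.

Two normalization choices deserve comment:

* **Bin count.** The joint matrix has `n!·n!` bins, of which
  `n!·n! − 2·n!` survive the exclusion, so JPE is normalized by
  `log(n!·n! − 2·n!)`. This choice only fixes the scale of JPE; it does not
  affect orderings between groups or conditions.
* **Renormalization.** After zeroing the excluded cells, the retained mass
  is renormalized to sum to one before the entropy sum (default). This keeps
  JPE the entropy of a genuine distribution, bounded by the log bin count,
  hence `JPE_inv ≥ 0`. Whether reference implementations renormalize is not
  documentable from their outputs alone, so `renormalize = FALSE` exposes
  the variant that keeps raw retained probabilities, for sensitivity
  analyses. An uncorrected variant (`corrected = FALSE`, normalizer
  `log(n!·n!)`) is available for quantifying how much apparent coupling the
  exclusion removes.

If essentially all joint mass (all but `1e-9`) falls on excluded cells —
`y = x` or `y = -x` being the extreme cases — the pair is indistinguishable
from pure zero-lag mixing and `JPE_inv` is set to 0 with a warning. Scoring
such a pair as maximal coupling would defeat the correction's purpose.

### Numerical determinism

`jpe_inv(x, y)` equals `jpe_inv(y, x)` bit-exactly: the positive joint
counts are sorted before the entropy sum, so the floating-point summation
order cannot depend on channel order. Similarly, the permutation test
compares repartition statistics to the observed one with a `1e-9` relative
tolerance, so repartitions that tie the observed statistic count as
exceedances despite round-off, and subjects are put in a canonical
data-derived order before repartitions are drawn, making p-values exactly
invariant to which group is passed first.

## Parameters

* `n` (embedding dimension, default 4): number of samples per pattern.
  Larger `n` resolves more pattern structure but needs more windows for
  stable frequencies; the classical reliability rule `n! << T` is enforced
  at pipeline level as `n! ≤ epoch_len / 10` (the primitive functions only
  require `T ≥ (n−1)·tau + 1`, so that short-sequence unit analyses remain
  possible). The default 4 compensates for the patterns lost to the
  volume-conduction exclusion while staying well inside the rule for
  4,096-sample epochs.
* `tau` (time delay, default 1 sample): spacing of pattern elements. The
  alternative `tau_rule = "band"` applies
  `tau = round(fs / (3 · f_high))`, floored at 1 — small enough that
  patterns still resolve the fastest oscillation surviving the band filter.
  The formula yields non-integers; nearest-integer rounding is the
  least-surprising deterministic choice and can be overridden in the config.
* Bands (Hz): theta 4–8, alpha 8–13, beta 13–30, broadband 0.5–45. Band
  edges are half-open `[f_low, f_high)` so a shared edge belongs to the
  higher band; the filter is a per-epoch brick-wall FFT mask (DC always
  removed, no taper, no padding). Ringing from the rectangular mask is
  accepted as part of this windowless design; energy at off-bin tone
  frequencies can leak a few percent past the band edge.
* Epochs: 20 non-overlapping epochs of 4,096 samples from the start of the
  recording (3.2768 s at the 1,250 Hz default rate). Metrics are computed
  per epoch and averaged per subject before any group statistics.
* Relative power uses the broadband range 0.5–45 Hz as denominator — the
  same definition as the broadband analysis band.

## Group statistics

The per-ROI group comparison uses a nonparametric permutation test with the
absolute difference of group means as a two-sided statistic, 10,000 random
repartitions by default, and the add-one Monte-Carlo estimate
`p = (1 + #{T_perm ≥ T_obs}) / (n_perm + 1)`, which guarantees `p > 0` as
validity requires (`plus_one = FALSE` recovers the literal proportion).
Benjamini–Hochberg (independence variant, via `stats::p.adjust`) adjusts
p-values per band across ROIs; significance is declared at `q < 0.05`.

Classification uses an unregularized single-feature logistic regression on
the ROI-averaged feature, an in-sample ROC over the fitted probabilities
(trapezoidal AUC with midrank ties, via pROC) and a DeLong 95% CI —
deterministic and testable, unlike bootstrap intervals. In-sample AUCs are
optimistic by construction; with these cohort sizes no cross-validation is
attempted. For an informative feature the AUC is invariant under monotone
transforms of the feature; for an uninformative one the in-sample
orientation itself is not identifiable. Perfect separation is flagged, and
the AUC — a rank statistic — is still valid. The confound check is a
one-way ANCOVA (`outcome ~ covariate + group`), reporting the group term's
F with `(1, N−3)` degrees of freedom and partial
`eta² = SS_group / (SS_group + SS_residual)`.

## The synthetic cohort generator

No clinical recordings ship with the package; a generator produces
two-group cohorts with known ground truth so that every stage is testable.
Each ROI is a sum of unit-variance components:

* a dominant AR(2) resonator at `osc_freq` (default 10 Hz, bandwidth 2 Hz),
  the alpha-peaked background of a resting-state recording, with coefficients
  from the standard pole-placement mapping (radius `exp(-pi·bw/fs)`, angle
  `2·pi·f0/fs`);
* an irregular theta AR(2) at 6 Hz with a deliberately wide 3 Hz bandwidth,
  mixed in with weight `theta_fraction` — arrhythmic theta activity rather
  than a clean rhythm;
* a common drive: one narrowband 6 Hz AR(2) (bandwidth 0.5 Hz, hence a long
  autocorrelation) shared by all ROIs with weight `coupling`, ROI `i`
  receiving it delayed by `(i−1)·coupling_lag` samples (default 10 samples,
  8 ms at 1,250 Hz — a conduction-like delay). Every pair therefore shares
  the drive at a non-zero relative lag, so genuine coupling is not removed
  by the zero-lag exclusion, and the drive's slow envelope keeps distant
  pairs weakly dependent;
* a 1/f background of weight `noise_sd`, built by spectrally shaping white
  noise (amplitude `f^(-1/2)` above a 0.5 Hz floor, DC removed).

Optional zero-lag leakage mixes each channel with the mean of its two ring
neighbors: `x_i <- (1−lambda)·x_i + lambda·mean(neighbors)`. This is the
adversarial input for the correction: it adds instantaneous dependence that
the corrected JPE_inv should ignore.

The default cohort templates contrast a control-like group
(SCD: `osc_freq = 10`, `theta_fraction = 0.15`, `coupling = 0.6`) with a
patient-like group (MCI: `osc_freq = 8`, `theta_fraction = 0.45`,
`coupling = 0.3`). The template differences encode the early-AD
phenomenology the pipeline is meant to detect: oscillatory slowing (the
dominant peak drifting toward the theta edge plus more arrhythmic theta)
raises relative theta power and theta-band PE, and weaker coupling plus the
higher local entropy both lower theta JPE_inv. Groups default to 18 + 18
subjects; per-subject `coupling` and `theta_fraction` are jittered ±10%
(uniform) and per-subject seeds are derived from the master seed, so a
cohort is fully reproducible from its spec.

What the generator does *not* emulate: biophysical neural-mass dynamics,
realistic forward-model field spread (leakage here is a simple ring mixing),
artifacts, non-stationarities, or between-ROI heterogeneity of spectra.
Passing tests therefore demonstrate that the measures recover the modeled
effects (lagged coupling, spectral slowing, added leakage) — not that they
would behave identically on clinical recordings.

## Problem sizes used in the test-suite experiments

The packaged experiments choose sizes that make their effects measurable
with comfortable margins while keeping a full run convenient on a laptop:
oracle-equivalence checks use hundreds of short sequences (`T ≤ 60`,
`n ∈ {2,3}`); analytic limits use `T = 1e5`; leakage and
coupling-recovery experiments use 6–8 ROIs with 2–8 epochs over 20 seeded
realizations; null calibration uses 50 runs of 18-vs-18 × 80 features at
2,000 repartitions (features drawn i.i.d. Gaussian — permutation-test
calibration depends only on exchangeability, not on the feature
distribution); the end-to-end study runs the full default cohort (18 vs 18,
80 ROIs, 20 × 4,096-sample epochs) in the theta band.

## Known limitations

* The brick-wall filter's ringing and the absence of artifact handling are
  accepted as part of the windowless epoch-wise design.
* In-sample AUCs overstate out-of-sample discrimination.
* The coarse-graining multiscale procedure is deliberately out of scope;
  band filtering combined with the `tau` rule plays that role.
* JPE_inv mixes local complexity and interregional coupling by
  construction; interpreting group differences requires reading it next to
  local PE, as the pipeline's outputs encourage.
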