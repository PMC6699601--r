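---
title: "Modeling team neurodynamics: symbols, entropy, and neurodynamic information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling team neurodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teamneuro)
```

## The model

Team neurodynamic modeling transforms microvolt-scale EEG dynamics into
informational units of team organization. The pipeline has four stages:

1. **Per-second band power.** Each member's recording is split into
   non-overlapping 1-s epochs; a tapered periodogram yields power in forty
   1-Hz bins (1–40 Hz) per sensor. With 1-s epochs the frequency resolution
   is exactly 1 Hz, so each bin holds one Fourier coefficient.
2. **Discretization.** Every (member, sensor, bin) stream is cut at its own
   empirical 33.33rd/66.67th percentiles, computed over the whole analyzed
   recording, into low (−1), average (1) and high (3) power levels.
3. **Team symbols.** The members' simultaneous levels form an ordered tuple,
   encoded in base 3 with member 1 as the most significant digit: a
   bijection onto `0..3^n − 1` (27 symbols for a triad). The per-second
   symbol sequence per (sensor, bin) is a neurodynamic data stream.
4. **Neurodynamic information.** A 60-s moving window, updated each second,
   yields the plug-in entropy of the windowed symbols;
   `NI(t) = log2(S) − H(t)` (bits) is reported at the window's end.
   Persistent symbol patterns — organization — give high NI regardless of
   whether the underlying power is persistently high or persistently low.

The central modeling assumption is that *persistence*, not power direction,
carries the team-level signal: a member locked in low gamma power is as
organized as one locked in high alpha power. NI deliberately discards the
microvolt meaning and keeps only the predictability of the joint state.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| window | 60 | s | long enough to resolve 27 symbols above the bias floor, short enough to track metastable episodes (>10 s) |
| step | 1 | s | symbol rate is 1 Hz; per-second NI supports real-time use |
| levels | 3 | — | tertiles maximize baseline entropy with interpretable low/average/high categories; `n_levels = k` gives `k^n` states at exponential data cost |
| missing tolerance | 20% | of window | beyond this the window is reported missing rather than silently computed on fewer symbols |
| shuffle count R | 100 | — | stabilizes the pooled 25th/75th percentiles of the null |
| max lag | 60 | s | cross-correlation search range, matching the window length |
| event padding | 60 | s | one full window of context on each side of an event |

Tertile thresholds are *per stream over the whole recording*. Balanced
categories put every disorganized stream at the same entropy ceiling, so NI
peaks are deviations from a common floor; they also make the symbolization
invariant under any strictly monotone transform of power (gain differences
between headsets, log scaling) — a property the test suite checks
explicitly. Boundary ties go to the lower category; a constant
(degenerate) stream maps to the average level. The mean ± 1 SD alternative
is available (`method = "mean_sd"`) but not default: it reacts to the
power distribution's shape, which tertiles ignore.

## Alignment and missing data

NI is timestamped at the window *end* (causal alignment): `NI(t)` uses only
symbols up to `t`, so the first `window − 1` seconds are a warm-up and an
epoch's NI response can trail its end by up to one window. A centered
alignment is available via `align = "center"`. A second where any member is
missing makes the team symbol missing; windows with more than 20% missing
symbols are missing. Missing power is a sentinel (`NA`), never zero — zero
is a valid power.

`Hmax` is computed as `log2(S)`: 1.585 bits for member streams, 3.17 bits
for 9 symbols (dyads), 4.755 bits for 27. These constants are computed,
never hard-coded, throughout the package.

## The plug-in bias floor and the shuffle baseline

The plug-in entropy of 60 draws from 27 equiprobable symbols
underestimates `log2 27`, so even i.i.d. streams show a positive NI floor
(≈ 0.4–0.6 bits; the suite pins it to `[0.2, 0.9]` by Monte-Carlo against a
counting oracle). No bias correction is applied by default, keeping the
estimator simple and the floor explicit; Miller–Madow is available
(`miller_madow = TRUE`). Instead of correcting, observed NI is compared
with a *randomized baseline*: each member's level stream is permuted
uniformly over its non-missing positions, team symbols are rebuilt, NI is
recomputed, and the 25th/75th percentiles are pooled over shuffles and
seconds. Pooling over time (rather than per second) is the default because
the null is stationary by construction. The permutation destroys temporal
structure while preserving marginals; a block-shuffle variant
(`block_s = 60`) preserves short-range autocorrelation for AR-like data.

## The synthetic generator

The generator emulates per-second power tensors, not physiology. Background
log-power is standard normal per stream — power is positive and
right-skewed, and the marginal's tertiles split levels uniformly — i.i.d.
by default, AR(1) (`phi = 0.6`, unit stationary variance) optionally. Real
recordings' power distribution is unknown; rank-based tertiles make every
downstream result invariant to this choice, which is why the null is a
modeling convenience rather than a claim about EEG.

Organization epochs force designated streams into a target tertile with
probability `occupancy` (> 1/3, chance level). Forced values are drawn by
inverse-CDF sampling from the *interior* of the target tertile (outer half
for ±, middle for average): an epoch inflates its level's share of the
recording, dragging the whole-recording empirical cut toward the forced
distribution, and interior sampling keeps forced seconds on the correct
side of the shifted cut for epochs up to roughly 20% of the recording.
Team-level epochs share one occupancy coin per second across members, so
the forced *team symbol* attains the configured occupancy.

Coupling replicates a leader's level pattern in a follower at a signed lag,
resampling the follower's power from its own values within the matching
tertile (marginals preserved, symbolic dynamics locked). The thresholds
used are attached to the result so replication can be verified exactly with
frozen cuts.

Synthetic raw EEG is a sum of per-bin sinusoids with per-second amplitude
modulation plus white noise — enough to exercise the spectral stage, with
no 1/f background, volume conduction or artifacts. Passing tests therefore
demonstrate the *pipeline's* correctness on streams with known symbolic
structure, not robustness to real-world EEG contamination, which is
declared upstream preprocessing.

## Numerical and design choices

- **Taper.** 1-s epochs with a Hann taper by default. On a 1-Hz grid the
  Hann taper spreads a pure integer-Hz tone over three bins (center carries
  2/3), whereas the rectangular option (`taper = "none"`) concentrates it
  entirely — the suite asserts both behaviors. Hann is kept as default for
  its far better sidelobe behavior off the integer grid.
- **Cross-correlation** is Pearson on overlapping valid pairs at integer
  lags, best lag by maximum `|r|` with ties toward zero lag; positive lag
  means the first series leads. At least `3 × max_lag` overlapping valid
  seconds are required.
- **Rank tests.** The region contrast computes the rank-sum Z with tie
  correction directly (the normal approximation, no continuity correction);
  below 20 samples per side without ties the exact p-value is used.
  Kruskal–Wallis across events uses the standard H with tie correction.
  Raw p-values are reported with no multiplicity correction; callers doing
  several contrasts should report the count of tests.
- **Fold ratio** in the region contrast is the ratio of means — a
  convention, stated in the output, since "n-fold greater" is otherwise
  ambiguous.
- **Aggregation order.** Band and scalp averages are pooled means over the
  contributing (sensor, bin, second) NI values; averaging frequency-first
  and sensor-first coincide only for complete data, and pooling is the
  well-defined choice under missingness.
- **Determinism.** Every stochastic routine takes a seed and restores the
  caller's RNG state; identical configuration and seed give byte-identical
  artifacts, which the suite checks by hashing pipeline outputs.

## Problem sizes

The test and acceptance runs use deliberately small instances: recovery
suites use 3-member teams with 1–2 sensors and 1–2 bins over 400–600 s and
20 seeds with `R = 100` shuffles; the demonstration workflow under
`analysis/` uses the full 6-sensor, 40-bin montage over an 800-s scenario.
These sizes put Monte-Carlo estimates (recovery rates, exceedance
fractions) well inside their tolerance bands while keeping any run under a
minute per stage.

## Known limitations

- The generator's null (lognormal background) is a convenience; only
  rank-level properties should be read off synthetic runs.
- Epoch forcing is guaranteed only for epochs shorter than ~20% of the
  recording; a level can never occupy more than a third of a recording
  under whole-recording tertiles, so very long "epochs" are ill-posed.
- The spectral stage expects integer sampling rates and clean input; EDF
  ingestion, re-referencing and artifact removal are out of scope, with CSV
  as the raw-exchange format.
- NI quantifies persistence, not interaction: transfer-entropy-style
  member-to-member information flow is deliberately not implemented.
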