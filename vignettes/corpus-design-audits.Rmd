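---
title: "Auditing the design of sleepiness speech corpora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing the design of sleepiness speech corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnaudit)
```

## The problem

Automatic detection of sleepiness from voice has stalled well short of
clinical usefulness, and a growing body of evidence points at the corpora
rather than the classifiers: datasets in which a handful of speakers
contribute orders of magnitude more recordings than the rest, clinical
labels whose distributions are dominated by a measurement ceiling, covariate
imbalances (sex, age, BMI) that let a model discriminate demographics
instead of sleepiness, and recordings too short for the standard acoustic
feature sets to stabilize. `somnaudit` packages those checks as a pipeline
that runs on any corpus manifest, together with a synthetic corpus generator
that reproduces the statistical structure the audits look for — so every
stage can be validated end to end without access to restricted clinical
recordings.

## Labels and their semantics

Three clinical instruments are built in as binarization rules mapping a raw
label to the sleepy (SL) / non-sleepy (NSL) classes:

* **KSS** (`kss7.5`): the Karolinska Sleepiness Scale, a 1–9 (or 1–10)
  self-report of instantaneous sleepiness, valid over roughly a ten-minute
  window. SL above 7.5 — the level above which micro-sleep events appear
  under EEG monitoring.
* **MWT** (`mwt19`): the Maintenance of Wakefulness Test, four 40-minute
  sessions in which the patient resists sleep; the label is the EEG-scored
  sleep latency averaged across the four sessions. SL below 19 minutes.
  Sessions without sleep onset are recorded as the 40-minute ceiling.
* **MSLT** (`mslt8`): the Multiple Sleep Latency Test, five 20-minute nap
  opportunities measuring propensity to fall asleep; SL below the 8-minute
  narcolepsy cut-off, ceiling 20 minutes.

Three semantic choices are worth making explicit. First, thresholds are
*strict*: a value exactly at the threshold is NSL. KSS scores are integers,
so the 7.5 cut never lands on a value and the choice is vacuous there; for
latencies the convention keeps boundary cases on the non-pathological side.
Second, the averaged latency is only defined when the full iteration set is
present — `average_latency()` returns a missing value for incomplete
protocols rather than a mean over fewer sessions, because a partial average
is not the validated clinical measure. Third, sample-level and
speaker-level classes are always derived independently: a sample's class
comes from its own per-iteration label, never from its speaker's trait
label.

The ceiling ("saturation") deserves emphasis: a latency equal to the test
maximum does not mean the patient took exactly that long to fall asleep —
it encodes the qualitatively different outcome that sleep never happened.
`saturation_fraction()` measures that mass (with a `1e-9` tolerance on the
equality so values survive a CSV round trip), and the audit report carries
it for every latency label.

## The audit statistics

Numeric covariates are compared between classes with a two-sided
Mann-Whitney U test; categorical covariates with a chi-squared test on the
2×2 class-by-category table. Two numerical-compatibility decisions matter:

* **Yates' continuity correction is the default** for 2×2 tables. On the
  published per-class tables of the clinical corpora this package mirrors,
  the corrected statistic reproduces the printed p-values
  (9.6×10⁻³, 0.16, 0.15, 0.056, 0.21) to printed precision, while the
  uncorrected one does not — this is checked in the test suite. The
  correction term is floored at zero so exact independence gives statistic
  0 and p = 1.
* **The Mann-Whitney branch is recorded.** The exact null distribution is
  used when `n1*n2 <= 400` with no ties, otherwise the normal approximation
  with tie and continuity corrections; the `method` tag says which branch
  ran, since published analyses rarely state theirs. The cutoff trades
  enumeration cost against approximation accuracy; at the boundary
  (20 × 20), exact and approximate p-values differ by well under 0.01.

Spearman correlations use midranks and the t approximation. No
multiple-testing correction is applied across audit rows: the mirrored
analyses report raw per-test p-values, so the report instead states the
number of tests performed and leaves the adjustment to the reader. With
the default α = 0.05, one in twenty independent null covariates will be
flagged; the calibration tests quantify exactly that.

## The synthetic corpus generator

The generator is the package's study-condition bench: it produces corpora
with the structure the audits assume, plus injectable design flaws.

* Each speaker has a latent sleepiness **trait** θ ~ N(trait_mean,
  trait_sd²); each session has a **state** s = θ + N(0, state_sd²).
* **Latency**: Gamma with shape 2 and mean `latency_scale · exp(−s)`,
  clipped at the schema ceiling. The Gamma family is a choice, not a fact
  about the clinic — it is right-skewed, nonnegative, and produces the
  ceiling spikes the real label histograms show. The defaults
  (`latency_scale` 60 min for the 40-min schema, 15 min for the 20-min
  schema) put roughly 60% and 26% of session latencies at the ceiling,
  the orders of magnitude reported for the corresponding clinical corpora.
* **KSS**: an equal-width discretization of `plogis(s)` onto the scale,
  ties broken toward the lower score (conservative toward NSL). Monotone
  in the state by construction.
* **Covariates** (sex, age, BMI, Epworth score) are independent of the
  trait unless a confound is injected with `inject_covariate_confound()`:
  strength 0 is independence, strength 1 deterministic coupling, and
  intermediate strengths mix the standardized trait with fresh noise so
  the covariate's marginal distribution stays fixed.
* **Determinism**: one master seed fans out to per-entity child seeds
  keyed by speaker and sample ids, so the same configuration is always
  bit-identical and adding a speaker never perturbs existing draws.

Utterance audio is optional and deliberately non-naturalistic: a harmonic
source (sine fundamental plus pulse train) whose F0 shifts linearly with
the state, a state-dependent spectral-balance filter, resonators at three
formant-like frequencies, and white noise at a configured SNR. No effect
sizes linking sleepiness to acoustics are established in the literature
this package draws on, so the acoustic defaults are placeholders with
controllable, monotone state effects — sufficient to test the feature
machinery, silent about real sleepy speech. Passing audits on this
generator therefore demonstrates that the *pipeline* detects the structures
it claims to detect, not that real corpora are clean.

## Minimum sample length by feature convergence

The question: how long must a recording be before the standard acoustic
functionals stop changing with additional audio? The procedure slices every
recording into nested prefixes of 1, 2, 3, … seconds, extracts a feature
vector from each prefix, and, for each length n, tests every feature
between the population at n and at n + 1 seconds with an unpaired
Mann-Whitney test. The curve r(n) — the fraction of features with p < α —
falls as features stabilize; its floor is α itself (the false-positive
rate), not zero, which the null-calibration tests assert. The recommended
minimum length is the smallest n from which r stays at or below θ = 0.15;
both this rule and the older cosine-similarity rule (converged when
consecutive-prefix similarity reaches 0.95 *and stays there*) use sustained
crossings, never first crossings.

Design choices where the procedure was underspecified:

* **Prefixes, not disjoint chunks.** Slicing is read as nested prefixes
  starting at sample zero: vectors at n and n + 1 are then maximally
  comparable and the whole procedure is deterministic.
* **Unpaired tests, uncorrected.** The samples at n and n + 1 are largely
  the same recordings, so a paired test would be more efficient; the
  unpaired pooled comparison is kept as the primary contract for fidelity
  to the published description, with `paired = TRUE` exposed as an
  extension. Likewise no multiplicity correction is applied over the
  feature set, with the documented consequence that the curve floors at α.
* **Shrinking rows.** The matrix at length n contains every sample of
  duration at least n, so row counts fall with n and curves for different
  corpora end at different lengths.
* **Causal internals.** Delta coefficients and spectral flux are backward
  differences (first frame zero), so the features of a prefix equal the
  features of the truncated file exactly — asserted to machine precision
  in the tests. Degenerate functionals (moments of a constant trajectory,
  spectral moments of silence) default to 0 and are counted.

The built-in extractor computes 19 low-level descriptor trajectories
(F0, RMS energy, zero-crossing rate, spectral centroid/roll-off/flux,
13 MFCCs) plus causal deltas, summarized by 11 functionals — 418 features.
It is a compact stand-in for the several-thousand-feature openSMILE
challenge sets; the adapter contract (`extract_features_external()`) lets
such an extractor drop in, since the convergence machinery only sees
matrices.

The headline numbers published for the restricted clinical corpora (a
20-second minimum, 15%/25% non-convergence at particular lengths) require
those corpora and are not reproducible here. What the package asserts
instead, on synthetic study conditions with fixed seeds, is the behavior
that makes such numbers meaningful: on stationary utterances (40 samples of
30 s) the curve stays below 0.15 from 10 s on, and on utterances with a
strong injected early drift — the state ramps 3 units and the amplitude
from 30% of its final level over the first 10 s, an unambiguous flaw by
design, since the probe checks detection, not threshold sensitivity — the
curve exceeds 0.25 within the first 8 s.

## Problem sizes

The validation suite and the reproduction script use: 2,000 simulations for
the Mann-Whitney null; a 60-row × 200-feature × 20-length table for curve
calibration; 100 generator seeds at 150 speakers for confound power
(flagged at a pinned rate of 0.82 at strength 0.6) and 200 seeds × 3
covariates at 100 speakers for false-positive calibration; 500 speakers ×
4 sessions for saturation recovery; and 40 × 30 s utterances for the
stationarity contrast. These sizes keep every Monte-Carlo band at three
binomial standard errors or wider.

## Known limitations

* The audits detect imbalance; they do not repair it (no matching, no
  causal adjustment).
* The generator's acoustic model is a placeholder: no phonetic content, no
  prosody, no validated sleepiness effect sizes. Results on synthetic audio
  validate the machinery only.
* Feature convergence is a property of the feature set, not of sleepiness:
  a converged feature vector is stable, not necessarily informative.
* The guideline linter covers only the quantifiable recommendations
  (lengths, equal sampling, metadata presence, questionnaire spacing, raw
  labels); judgment calls — text choice, recording environment, population
  selection — are out of its reach.
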