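---
title: "Rest and activity phenotyping from capacitance home-cage monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rest and activity phenotyping from capacitance home-cage monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagerest)
library(dplyr)
```

## The measurement problem

Capacitance-based home-cage monitoring racks place an electronic board with
12 capacitance-sensing electrodes under each cage and record, continuously
and without disturbing the animals, the capacitance changes induced by the
two co-housed mice moving above the board. This makes it possible to study
rest-related behaviour in frail disease models for which EEG implantation or
laboratory sleep tests are not an option. `cagerest` implements the full
analysis chain from raw capacitance tables to longitudinal group statistics,
together with a generative simulator used to validate every stage.

The chain has four stages:

1. **Activation.** An electrode counts as *activated* when the absolute
   difference between two consecutive capacitance samples exceeds a fixed
   threshold $\lambda$, chosen to separate electronic noise from animal
   movement. The per-minute **activity index** is the activation density:
   activated (electrode, sample-pair) cells divided by all unmasked cells in
   that minute, a number in $[0, 1]$. A second, much lower threshold
   ($\lambda = 1.25$ applied to differences of consecutive 1-s average
   windows) defines the per-second binary **immobility** series: a second is
   immobile only if *no* electrode saw a supra-threshold change, i.e. both
   mice were still. Rest metrics use this lowest usable threshold so that
   even slow or small movements count as activity.

2. **Regularity Disruption Index (RDI).** For each cage, day and 12-h phase,
   the per-minute activity segment is band-pass filtered (zero-phase
   Butterworth) and its **sample entropy**
   $\mathrm{SampEn}(m, r) = -\ln(A/B)$ is computed, where $B$ counts pairs of
   length-$m$ templates within Chebyshev distance $r$ and $A$ the same pairs
   extended to length $m+1$, excluding self-matches. RDI near 0 means minute
   activity levels that are all very similar (consolidated, rest-like
   behaviour); fragmented activity, where successive minutes differ
   irregularly, gives high RDI.

3. **Zero-activity analytics.** From the immobility series: the percentage
   of zero-activity time per hour post lights-on; the **least active
   consecutive hour** (the 60 consecutive minutes with the lowest mean
   activity over the 24-h day — its occurrence in the dark phase is the
   daytime-sleepiness-like signal in a nocturnal species); **rest bouts**,
   maximal runs of immobile seconds of at least 40 s (the established
   behaviourally-defined sleep proxy in mice); time-weighted bout-duration
   histograms (<5, 5–15, >15 min bins, each bin weighted by the rest time it
   contains and normalized by total rest per phase); and the fraction of
   rest in bouts longer than 30 min.

4. **Statistics.** Cage-level weekly metrics enter a rank-based ANOVA-type
   test for the factorial longitudinal design (sex and genotype as
   between-cage whole-plot factors, week as the within-cage sub-plot
   factor), with Wilcoxon two-sample post-hocs under Bonferroni correction.
   The cage — not the animal — is the experimental unit throughout.

## Calendar conventions

All phase logic is anchored at lights-on (default 07:00, 12:12
photoperiod). An analysis *day* runs from one lights-on to the next, so both
12-h phases of a behavioural day stay together and "hour $h$ post lights-on"
indexes hourly summaries. Phase intervals are half-open
$[\text{on}, \text{off})$: a sample stamped exactly at lights-off is dark.
Whether days should instead be midnight-anchored is not decidable from the
data themselves; lights-on anchoring was chosen because every phase-resolved
metric in the package is defined relative to the photoperiod.

Days on which cages are changed are excluded before any aggregation —
husbandry visibly perturbs home-cage behaviour. Masked (missing) samples are
carried as `NA` and *removed from denominators*, never zero-filled, because
zero-filling would fabricate rest; masked seconds also terminate rest-bout
runs, so a sensor gap is never bridged into a bout.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `lambda` | 5 | capacitance units | graded activity threshold; vendor value unpublished, only its ordering above `lambda_immobility` matters for the package's guarantees |
| `lambda_immobility` | 1.25 | capacitance units | lowest usable threshold, on consecutive 1-s average windows |
| `fs` | 4 | Hz | sampling rate; densities depend only weakly on it |
| `smooth_window` | 3 | min | centred moving average for the smoothed index |
| `samp_en_m` | 2 | — | sample-entropy embedding dimension (standard convention) |
| `samp_en_r` | 0.2 | × SD | tolerance as fraction of the filtered segment's SD |
| `band_low_period`, `band_high_period` | 2, 120 | min | Butterworth passband period bounds |
| `filter_order` | 2 | — | Butterworth order |
| `bout_min` | 40 | s | minimum rest-bout length |
| `bout_bins` | 5, 15 | min | interior bin edges of the duration histogram |
| `long_bout_threshold` | 30 | min | long-bout cut |

`samp_en_m = 2` and `samp_en_r = 0.2·SD` are the standard sample-entropy
conventions, not vendor values; because $r$ is computed per phase segment
after filtering, light and dark are each self-normalized, and RDI is
invariant to affine rescaling of the activity index.

### The filter edge case

For a 1/min series the Nyquist period is 2 min, so the default
`band_low_period = 2` puts the upper band edge exactly at Nyquist, where no
discrete band-pass exists. The filter then degrades gracefully to the
realizable part of the specification: a high-pass at `1/band_high_period`
that removes the DC level and circadian trend while keeping all
supra-Nyquist-adjacent structure. Any `band_low_period` above 2 min yields a
true band-pass; its measured gain matches the closed-form Butterworth
magnitude response (bilinear-transform design with prewarped edges) to
within 1%, and filtering is implemented forward–backward with odd-reflection
padding long enough for the slow low-edge transient, so it is zero-phase and
returns exactly 0 on constant input.

### Degenerate sample-entropy counts

Automated pipelines must not produce infinities: if no length-$m$ template
pair matches ($B = 0$) the RDI is undefined and flagged; if matches exist at
$m$ but none persist at $m+1$ ($A = 0$) the capped estimate $-\ln(1/(B+1))$
is returned and flagged. A zero-variance (constant) filtered segment returns
RDI 0, the regularity limit. Phase segments with more than 20% masked
minutes are flagged `low_confidence`; masked minutes are linearly
interpolated before filtering.

### Ties and tie-breaks

The least-active-hour search scans all 1381 non-wrapping start offsets of a
day and breaks ties at the earliest start, making results deterministic.
Windows with more than 10 masked minutes are skipped. A rest bout straddling
the lights-off boundary is attributed once, to the phase of its onset
second. Rank statistics use mid-ranks for ties throughout.

## The ANOVA-type statistic

The longitudinal test ranks all cage × week observations jointly and forms,
per (sex, genotype, week) cell, the mean rank (equivalently the relative
treatment effect $\hat p = (\bar R - 1/2)/N$). For an effect with projection
matrix $T$ (a Kronecker product of centring and averaging matrices over the
three factors) and $\hat V$ the block-diagonal estimate of the covariance of
the cell mean ranks (cages independent, weeks correlated within cage), the
statistic is

$$ F = \frac{q^\top T\, q}{\operatorname{tr}(T \hat V)}, \qquad
   \hat f = \frac{\operatorname{tr}(T\hat V)^2}{\operatorname{tr}(T\hat V T\hat V)}, $$

referred to $F(\hat f, \infty)$ — the Box approximation, which yields the
possibly non-integer degrees of freedom familiar from rank-based
longitudinal analyses (two-level factors give exactly $\hat f = 1$). The
Wald-type alternative is deliberately omitted: at 8–11 cages per group its
covariance estimate is unstable, and the ANOVA-type form is the one used in
this literature. The implementation is validated by simulation rather than
against an external reference: under exchangeable null data at the study's
group sizes (10/10/11/8 cages, 5 weeks) the acceptance suite requires the
genotype test's rejection rate to sit within 0.05 ± 0.02, and the power test
requires a large additive genotype shift to be detected with $p < 0.001$ in
essentially every replicate.

Wilcoxon post-hocs use full-enumeration exact p-values for pooled samples of
at most 20 without ties, and the mid-rank normal approximation with tie
correction otherwise. Bonferroni families follow the figure panels: 24 hour
bins for the hourly percent-zero profile, the number of duration bins for
bout histograms.

## The synthetic cohort generator

No raw recordings of this kind are publicly deposited, so validation uses a
generative stand-in whose defaults encode the study conditions: four groups
(10 + 10 male, 11 + 8 female cages of wild-type and mutant), 5 weeks of
recording, 12:12 photoperiod with lights on 07:00–19:00, weekly cage
changes, two mice per cage.

Each cage alternates REST and ACTIVE states of a two-state semi-Markov
process with log-normal dwell times; parameters are selected by the phase
(and hour) at each dwell's onset, and dwells may straddle phase boundaries,
as real bouts do. Log-normal dwells are the simplest family producing the
heavy-ish bout-duration tails that populate all three histogram bins and
the >30-min cut. Active dwell means are derived from the rest dwell means so
that the renewal-theory stationary rest fraction
$E[\text{rest}]/(E[\text{rest}]+E[\text{active}])$ hits the configured
target: 0.65 in light, 0.35 in dark for controls — nocturnal, with roughly
two thirds of the light phase spent resting. REST seconds emit immobility 1;
per-minute activity is the active fraction of the minute times the group
activity level (0.25 for control males, ×1.3 for females — control females
are the more active sex — ×0.7 for mutants) under multiplicative Gaussian
noise (SD 0.12), clipped to $[0,1]$. The hourly circadian profile defaults
to flat within phases: the light/dark dichotomy already carries the
circadian structure that the package's phase-resolved metrics consume.

The mutant phenotype is injected as a single mechanistic change plus one
emission change: dark-phase rest dwell means are doubled (longer rest bouts
in the active phase — the headline phenotype) and activity level is scaled
by 0.7 (hypoactivity). Everything else — higher mutant dark percent-zero,
lower dark RDI, more weight in >15-min and >30-min bouts, more frequent dark
least-active hours — must *emerge* through the pipeline, which is exactly
what the acceptance suite checks.

What the generator does **not** emulate: within-phase circadian ramps,
ultradian feeding rhythms, sensor drift or electrode-level spatial
structure, inter-cage variability in baseline rest fractions, and age
trends across the 5 weeks. Passing tests therefore demonstrate the
*pipeline's* correctness and the *direction* of group contrasts under the
modelled mechanism, not biological effect sizes; printed statistics from
real cohorts are not reproducible from simulation and are not targets.

A capacitance-level emitter (`emit_capacitance()`) optionally inverts the
activation stage for testing: immobile seconds carry sub-threshold jitter,
active seconds place supra-threshold pulses on 1–3 random electrodes. The
consecutive-mean immobility rule has an inherent one-second smear (movement
in second $s$ raises that second's mean, so both adjacent comparisons
trip); round trips are therefore checked on seconds whose predecessor is
also immobile.

## Problem sizes used in validation

Simulation-based checks are sized to keep the full suite fast while leaving
the conclusions unambiguous: oracle-equivalence runs use 100 random
instances per metric; null calibration uses 1000 replicates at the study's
cage counts, generated at the weekly-metric level (the level at which the
tests operate); phenotype-direction checks run 100 cohorts of 4 cages per
group over 5 recording days; rest-fraction recovery uses full 5-week
single-cage series, where renewal averaging makes ±0.03 a comfortable
bound. The acceptance script additionally pushes one full study-scale
cohort (39 cages, 5 weeks) through the entire pipeline.

## Known limitations

- Per-cage, not per-animal: with two mice per board, immobility means *both*
  animals still, and no metric attributes activity to an individual.
- The vendor's exact activity metric, smoothing kernel, sampling rate and
  filter settings are proprietary and unpublished; this package fixes
  documented, configurable conventions instead, so absolute metric values
  are comparable within analyses run by this package, not with vendor
  output.
- Sample-entropy parameters and the passband are conventions (see above);
  numeric equality with any particular published RDI value is not claimed.
- The least-active-hour search does not wrap across the lights-on boundary;
  a rest period spanning lights-on is split between two days.
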