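---
title: "Methods: agreement and telemonitoring analytics for smartwatch vital signs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: agreement and telemonitoring analytics for smartwatch vital signs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearagree)
```

## The problem

Consumer smartwatches measure oxygen saturation (SpO2, %), blood pressure
(mm Hg) and heart rate (bpm) outside the clinic, but before such readings
can support clinical decisions their agreement with gold-standard devices
must be quantified under realistic, home-use conditions. `wearagree`
implements the complete analysis pipeline for this kind of validation
cohort: daily triplicate readings from a watch and a gold-standard device
are consolidated, paired, and summarized by repeated-measures limits of
agreement; per-volunteer means feed a two-group comparison; the continuous
heart-rate stream feeds a MANOVA profile analysis of the 24-hour circadian
curve; paired polysomnography/watch hypnograms yield sleep-architecture
metrics; threshold rules yield an alert tally; and platform ingestion
timestamps yield a synchronization-latency histogram.

Because validation cohorts of this kind are rarely deposited, the package
includes a first-class synthetic-data generator that emulates the
statistical structure the analysis consumes. Every stage of the pipeline
is therefore testable end to end without any external data.

## Preprocessing

Readings outside biological viability are discarded before analysis:
SpO2 outside [60, 100]%, blood pressure or heart rate outside [20, 300].
Continuous (passively sampled) data are further restricted to weekdays,
where daily routines are more comparable; manually collected readings are
kept regardless of day.

Manual readings arrive in same-session triplicates. With the replicates
sorted ascending ($v_1 \le v_2 \le v_3$) a tolerance region
$TR = 0.1\,v_1$ is computed and the first matching rule applies:

1. $v_3 - v_1 < TR$: average all three (`all_within`);
2. both gaps $< TR$: keep the middle value (`middle_only`);
3. exactly one gap $< TR$: average the middle value with that extreme
   (`pair_with_extreme`);
4. otherwise the spread is treated as genuine and all three are averaged
   (`none_within`).

Three reading choices were open and are fixed here: the "smallest region"
on which the 10% is computed is read as the smallest replicate $v_1$ (the
only reading that yields a well-defined scalar before any gap exists);
the precedence whole-range, then both-gaps, then one-gap makes the
overlapping prose conditions mutually exclusive; and all comparisons are
strict, with ties falling through to the next rule. Days without exactly
three viable readings per device are dropped with a logged count rather
than imputed. Exact ties sit on a measure-zero boundary where strict
comparisons are not stable under floating-point rescaling; the
property-based tests therefore exercise scale equivariance away from
ties only.

## Limits of agreement for repeated measures

Each volunteer contributes many paired watch/gold readings, so the
classic Bland-Altman limits would understate the variance of a fresh
difference. The package uses the fixed-effects one-way ANOVA
formulation: for differences $d_{ij} = \text{watch} - \text{gold}$ with
$n$ volunteers contributing $m_i$ pairs ($N = \sum m_i$),

$$ MSW = \frac{\sum_{ij}(d_{ij} - \bar d_i)^2}{N - n}, \qquad
   MSB = \frac{\sum_i m_i (\bar d_i - \bar d)^2}{n - 1}, \qquad
   m_0 = \frac{N - \sum_i m_i^2 / N}{n - 1}, $$

$$ \hat\sigma_b^2 = \max\!\left(0, \frac{MSB - MSW}{m_0}\right), \qquad
   \hat\sigma_d^2 = \hat\sigma_b^2 + MSW, $$

with 95% limits $\bar d \pm 1.96\,\hat\sigma_d$ around the grand mean.
Choices: the bias is the grand mean over all pairs (not the mean of
volunteer means), which is what the unbalanced-replicates formulation
absorbs through $m_0$; a negative between-volunteer component is
truncated to zero and flagged; and 1.96 is used verbatim with no
small-sample t correction, matching the convention of the validation
literature this analysis follows. With $m_i \equiv 1$ the estimator
reduces exactly to the ordinary SD of the differences.

Around the limits sit three descriptive companions: band fractions (the
percentage of pairs with $|d|$ within 1/2/3% for SpO2, 5/10/15 mm Hg for
blood pressure, 1/2/3 bpm for heart rate; thresholds are inclusive),
an ordinary least-squares trend of $d$ on the gold value whose zero
crossing (`center`) is the value around which the watch appears
calibrated, and a naive Pearson correlation that is reported with an
explicit dependence caveat since repeated pairs are not independent.
Group-wise limits reuse the same estimator per group; no test statistic
is attached, since the method provides none for comparing limits.

## Group comparisons and profile analysis

Per-volunteer means over available days (separately per device) are
compared between groups with Welch's two-sample two-tailed t test, and p
values are Holm-adjusted across the four vitals within each device.
Welch rather than pooled-variance is the deliberate default where the
method is stated only as a "t test for independent samples"; Holm is the
adjustment chosen where an adjustment is stated but unnamed.

The continuous weekday heart-rate stream is reduced to one 24-position
vector per volunteer (mean per clock hour within day, then across days).
Volunteers missing any clock hour are dropped from the multivariate
analysis and listed, rather than imputed. Profile analysis then tests:

* **level** — one-way ANOVA F on the profile grand means;
* **flatness** — one-sample Hotelling $T^2$ on the 23 successive-hour
  differences with all volunteers pooled,
  $F = \frac{N-p}{(N-1)p} T^2$ on $(p, N-p)$ df, which makes the test
  exactly invariant to group labels;
* **parallelism** — Wilks' $\Lambda = \det(E)/\det(E+H)$ for the group
  effect on the difference vectors, with Rao's F approximation (exact
  for two groups).

The successive-differences contrast is one of many full-rank choices
that give identical $\Lambda$; averaging to hourly profiles first means
the minute-scale autocorrelation of the raw stream is absorbed into the
multivariate covariance rather than modelled. The Wilks computation is
authored in the package and cross-checked in the tests against
`stats::manova`, which is never used as the implementation. With 23
contrasts the tests require at least $p + g$ complete profiles; below
that the function errors and advises aggregating hours.

## Sleep metrics

Polysomnography scores 30-second epochs over awake/N1/N2/N3/REM; the
watch reports summarized intervals over awake/light/deep/REM and starts
recording only at the first detected sleep stage. Harmonization maps N1
and N2 to light and N3 to deep, merging adjacent epochs into intervals
(total duration preserved exactly). Time in bed (TIB) for the gold
record spans report start to report end; for the watch it spans the gold
start to the start of the last awake interval the watch recorded.
From a four-stage record and a TIB window the summary computes sleep
latency (TIB start to first sleep), total sleep time (TST = light +
deep + REM within TIB, intervals truncated at the TIB end), sleep
efficiency ($SE = 100 \cdot TST / TIB$), and wake after sleep onset
(WASO). Awake time before sleep onset counts toward latency, not WASO,
which is what makes the identity awake = latency + WASO hold. All
durations live on a 1-second grid since reports print h:mm:ss. With a
handful of paired nights the comparison is descriptive only.

The packaged `sleep_sessions` reference table carries the printed
session times of eight paired nights from a published validation cohort;
the tests recompute TIB, latency and SE from those timestamps exactly.
One caveat encoded in the tests: printed latencies are timestamp
differences and need not be multiples of the 30-second epoch, so the
awake = latency + WASO identity holds on the printed gold rows only to
within one epoch.

## Alerts and accounting

Default alert rules are systolic $\le 70$ or $> 180$ mm Hg, diastolic
$\le 40$ or $> 120$ mm Hg, SpO2 $< 88$%, heart rate $\le 40$ bpm. The
boundary conventions differ between narrative and tabulated statements
of these rules in the validation literature; the comparators here follow
the narrative form and every rule is config-overridable, so the
alternative inclusive readings are one argument away. The report tallies
events and distinct volunteers per rule, including zero rows.

Synchronization delays (platform ingestion minus acquisition) are binned
into the standard reporting bins, read as contiguous half-open intervals
with upper-inclusive printed bounds — (0, 1 h], (1 h, 2 h], (2 h, 6 h],
... (14 d, Inf) — the only partition under which accumulated percentages
reach 100. A delay of exactly 14 days therefore bins to "8-14 d".
Percentages are rounded half-up at the precision the report tables
print (2 decimals for shares, 1 for cohort percentages). Cohort
accounting (recruitment funnel, active users per follow-up block,
follow-up-duration distribution) and the record-type tally recompute all
percentage columns from raw counts; enrollment/dropout streams are
validated so a dropout can never precede its enrollment.

## The synthetic generator

The generator's defaults are the study conditions: 40 volunteers per
group (75% female, with the reference cohort's race and age-band
composition allocated by largest remainder so default proportions are
exact), 60 consecutive daily triplicate visits, and 7 days of
minute-level continuous heart rate.

For each volunteer-day and variable a latent true value is drawn around
a volunteer-level mean; the gold device adds replicate noise, and the
watch adds an additive offset, a linear error trend
$\beta (x - c)$ for the blood pressures ($\beta = -0.39$, $c = 82$ mm Hg
diastolic; $\beta = -0.36$, $c = 124$ mm Hg systolic), a day-level
device error shared by the triplicate, and replicate noise; SpO2 from
either device is capped at 100% after noise, which reproduces the
fan-shaped Bland-Altman pattern near the ceiling. Drawing the latent
value per volunteer-day around volunteer-level means makes the
between/within variance decomposition of the repeated-measures limits a
real feature of the data, not an artifact. The noise scales are set so
the generator reproduces the reported agreement moments: realized mean
differences of $-1.28$%, $-1.399$ and $-1.536$ mm Hg and $+0.566$ bpm,
and difference SDs of 2.897, 9.75, 12.37 and 1.589. Two offsets differ
from the realized means by construction: the SpO2 ceiling shifts a
$-0.98$ offset to a $-1.28$ realized mean, and the blood-pressure trend
term contributes $\beta(\mu - c)$ on top of the additive offset. The
within/between variance split itself is not reported anywhere and is a
free choice here; recovery checks are therefore made against the
generator's own implied moments (`expected_agreement()`, a model-level
Monte Carlo that is independent of the tabular pipeline), not against
an external truth. Triplicate outliers (probability 0.03, magnitude 20%
of the reading, random sign) are large relative to the tolerance region,
so consolidation isolates them — which is the scenario the tolerance
rules exist for.

The circadian template is a baseline plus Gaussian bumps for the morning
rise (centred 07:00) and post-lunch peak (13:30) and a circular
nocturnal trough (03:30), plus volunteer-level baseline offsets and
residual noise; the group effect on heart rate defaults to zero,
matching the absence of a group difference in the reference cohort.
Sleep sessions are built as semi-Markov stage sequences on the
30-second epoch grid (latency, five light/deep/REM cycles, brief
awakenings, final awakening); the watch record is derived from the gold
record by stage mapping, dropping the pre-sleep awake period, missing
brief awakenings below a 2-minute threshold with probability 0.7,
jittering internal boundaries (SD 2 min), reporting on a 60-second
resolution, and flagging the final awakening with a gamma-distributed
lag (mean 15 min) — the mechanism behind the watch's systematic TIB
overestimate and WASO underestimate in real paired nights.
Synchronization delays are a two-component lognormal mixture in hours
(weight 0.855 on lognormal(2.524, 0.887), the remainder on
lognormal(5.299, 0.669)), least-squares calibrated to the reported
cumulative delay distribution, putting about 66% of records within 24
hours and under 10% beyond a week.

All randomness flows from one root seed through fixed per-stream
substreams, so identical configurations give byte-identical outputs.

What the generator does not emulate: PPG waveforms or any physiology
beyond the moments the analysis consumes, heavy-tailed or skewed
replicate noise (differences are conditionally normal), device drift
over the study, missing-data mechanisms other than viability exclusions
and incomplete triplicates, and correlation between the manual vitals
and the continuous stream. Green tests therefore certify the
statistical machinery and its contracts on data with the assumed
structure; they do not certify the devices, nor robustness to artifacts
real wearables produce.

## Problem sizes and numerical choices

The test suite exercises the estimators at the scales the methods are
meant for while staying quick: the recovery check runs the full pipeline
on the default 80-volunteer, 60-day cohort (4800 pairs per variable);
limit coverage is checked on a 400-volunteer model simulation with
400,000 fresh differences (94-96% expected); the parallelism test's
type-I error is estimated from 100 seeded null replicates of an
80-volunteer cohort streamed at 5-minute resolution over one week
(weekdays retained), with rejection rate required at or below 10% at
$\alpha = .05$; and the consolidation rules are swept over a dense
triple grid. Degenerate inputs are contracted explicitly: a single
volunteer, empty pair sets, zero-variance regressors and correlation
inputs, watch records with no awake interval, and records that never
sleep all raise informative errors or flags rather than silent numbers.

## A worked run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
bundle <- run_pipeline(cfg, out_dir = "run1")
tidy(bundle$loa)
autoplot(bundle$loa)
tidy(bundle$profile_tests)
```

The bundle's manifest records the configuration hash, seed, package
version, row counts and exclusion tallies; reruns under the same
configuration are byte-identical, which the tests assert file by file.

## Known limitations

Confidence intervals around the limits of agreement are deliberately
not computed (the reporting convention followed here presents none), no
mixed-effects or random-slope agreement variants are offered, sleep
staging is consumed (not inferred from raw signals), and alert
evaluation is a batch tally, not a dispatch system. The published
agreement tables themselves derive from an undeposited cohort, so they
are encoded only as reference tables for identity checks, never as
fitting targets for the estimators.
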