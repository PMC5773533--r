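---
title: "Active/Inactive State analysis: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active/Inactive State analysis: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actistate)
```

## The behavioral model

Laboratory mice, like their wild relatives, organize spontaneous behavior
around a single sheltered nest site: long pauses occur there, and activity is
expressed in discrete excursions during which the animal feeds, drinks and
moves about the cage. `actistate` operationalizes this structure for
home-cage monitoring data. Each *mouse-day* (MD) is the event record between
consecutive daily maintenance periods: a 22 h observation window from
Zeitgeber time (ZT) 8 to ZT 6 (+24 h), since maintenance occupies ZT 6–8.
Times are seconds from ZT 0; the dark cycle is ZT 12–24.

Three event types are consumed: movement events (timestamp + position,
emitted on >1 cm displacement of the center of mass), and feeding and
drinking events (time intervals), plus per-day intake totals. All intervals
are half-open `[start, end)`, which makes every partition in the package
(states over the window, bins over the day, cells over the cage floor)
unambiguous: boundary points belong to the later/higher-indexed member.

### Home Base

Occupancy uses sample-and-hold interpolation: the animal occupies its last
recorded position until the next movement event. Movement events are emitted
only on displacement, so between events the position genuinely is (to 1 cm)
the last recorded one; before the first event we hold the first position
backwards to the window start. The coarse Home-Base grid is 4 cells along
the 45 cm length × 2 across the 24 cm width; the niche occupies exactly one
of the 8 cells. The designation cascade — niche-if-peak, then
single-majority, then best contiguous pair — is ordered from the
biologically expected case to fallbacks; pair ties are broken by lowest cell
index (a deterministic convention; ties are measure-zero in real data).
Full-MD occupancy (rather than IS-only occupancy) is used: it requires no
prior state designation, avoiding circularity between Home-Base and state
stages.

### State designation

Activity events are the union of all ingestion events and the movement
events outside the Home Base. Ingestion events count regardless of location
because the feeder and spout are intrinsically active-behavior sites, and in
strains that nest beside the feeder a position filter would delete genuine
feeding activity. Gaps of at most the Inactive State Threshold
(`ist_s`, default 1200 s = 20 min) are bridged; the resulting runs are
Active States (ASs), delimited exactly by their first event's start and last
event's end (no padding). Gaps *equal* to the threshold are bridged — this
reconciles the two equivalent phrasings of the rule ("pauses exceeding the
threshold are Inactive States" vs "gaps of length at most the threshold are
connected"). A record with no activity events yields zero ASs and one
window-long IS; a lone event yields a zero-length AS, retained so that AS
counts are monotone in the threshold.

`states_oracle()` re-derives the partition on a 1 s tick grid by brute
force and is used throughout the tests as an independent reference; with
event times on the tick grid the two routes agree exactly, interval by
interval.

### Features

Nine feature classes per MD over eleven 2 h bins (ZT 8–10 … 4–6). Choices
the definitions leave open were fixed as follows:

- An AS spanning a bin boundary contributes *time* to every bin it overlaps
  (AS Probability, AS Intensities) but is *counted* once, in its onset bin
  (AS Numbers, AS Durations). This keeps ASN a count and ASP a proper
  fraction of bin time.
- Ingestion amounts are prorated by fractional time overlap when an event
  straddles a bin edge, so intake is conserved across bins.
- A distance step between consecutive movement events is assigned to the bin
  (and AS) containing the *later* event's timestamp, making total distance
  invariant to bin refinement.
- Empty-bin AS Durations and Intensities are reported as 0, not missing, so
  downstream matrices stay complete; ASP distinguishes genuinely inactive
  bins anyway.

Daily-pattern correlations (Pearson and Spearman, via `stats::cor.test`)
compare 11-bin mean patterns with each group's pattern mean-centered before
pooling, so the statistic measures time-of-day covariation rather than
between-group level differences. Constant vectors are flagged rather than
propagated as NaN.

## The statistical battery

**Heritability.** The balanced one-way ANOVA variance-component estimator:
with $s$ strains, $n$ mice per strain, $N = sn$ per-mouse MD-averaged values
$\mu_{ij}$,
$MS_b = \frac{n}{s-1}\sum_i(\mu-\mu_i)^2$,
$MS_w = \frac{1}{N-s}\sum_{ij}(\mu_{ij}-\mu_i)^2$,
$V_g = (MS_b - MS_w)/n$ clipped at zero (the moment estimator can go
negative), $V_e = MS_w$, $H^2 = V_g/(V_g+V_e)$ (defined as 0 when both
components vanish). Bootstrapping draws half of each mouse's MDs
(`floor(k/2)`, at least 1) without replacement and subsamples a fixed
`n_per_strain` mice per strain to keep the design balanced; the subsample is
re-drawn per trial since no selection rule for over-sized strains is
canonical.

**Time budgets.** The event stream does not define "locomotion time"
directly; we operationalize it as the summed duration of *movement
episodes* — maximal runs of movement events with inter-event gaps at most
`locomotion_gap_s` (default 1 s, exposed in the API because it is a modeling
choice, not a measurement). Categories are made an exact partition of AS
time by priority masking (feeding over drinking over locomotion over other),
so budget vectors always sum to 1 even when event intervals overlap.
Kullback–Leibler divergence is computed in nats as `D(DC ‖ LC)` after adding
a pseudocount of 1e-6 per category and renormalizing; this keeps empty
categories finite while leaving well-populated budgets essentially
unchanged. Strain budgets pool time across the selected MDs (a per-mouse
averaging variant would weight animals equally instead; pooled time matches
the interpretation of a budget as "how the strain's time divides").

**Within-AS structure.** Each AS contributes a 180-bit string over the
15 min after onset (or before offset; bin 179 abuts the offset). Bins beyond
the AS extent score 0, and scoring is masked to the aligned AS so an event
belonging to a neighboring state is never attributed across states. The
null model scores windows identically but anchors them at `k` movement
events sampled uniformly without replacement per MD, with `k` the mouse's
rounded mean daily AS count; peaks (per-mouse maxima) are compared by
Welch's unequal-variance t-test. Identical constant groups give p = 1 by
convention.

**Discrimination.** The clustering accuracy score is computed exactly from
its counting definition; an empty predicted group contributes 0 to the
between-group subscore. Pairwise discrimination standardizes features on
train statistics, runs `stats::kmeans` with K = 2 and 10 restarts, and
assigns all items to the nearest train centroid — centroids are *not* refit
on test data. The strain classifier is one-vs-rest logistic regression with
an L2 penalty (`glmnet`, `alpha = 0`), regularization fixed at
`lambda = 1/(C · n_train)` with inverse strength C = 1 — a standard default;
no published value exists for this analysis. Mouse-level classification
averages each animal's held-out MD vectors and classifies the average.
PCA mean-centers columns, uses the population covariance `C = (1/n) MᵀM`,
and rescales projections to unit variance; eigenvector signs are fixed by
making each component's largest-magnitude loading positive. Zero-variance
features are dropped with a warning. Ellipsoid overlap samples uniformly in
the smaller ellipsoid's bounding box; the larger-volume ellipsoid (product
of semi-axes; lexicographic id on ties) acts as the container.

## The synthetic cohort generator

`simulate_cohort()` exists so that every stage has ground truth. Each MD is
an alternating renewal process: per 2 h bin $b$ a strain has a target AS
time fraction $f_b$ and mean AS duration $\bar{a}_b$ (exponential draws); IS
durations are a 21 min floor plus a gamma(shape 6) component whose mean
makes the expected AS fraction equal $f_b$. Two design points deserve
explanation:

- *The floor and the gap cap.* Within-AS event gaps are capped at 10 min and
  inter-AS gaps are at least 21 min, straddling the 20 min threshold with a
  margin on both sides. This makes state recovery at IST = 20 min *exact*,
  so the simulator can serve as an oracle for the parser.
- *The gamma (rather than exponential) excess.* Real records show nearly
  constant AS counts for thresholds between 15 and 30 min, which means real
  inactive pauses rarely last 15–30 min. An exponential excess above a
  21 min floor would put roughly half its mass in that band and make AS
  counts collapse as the threshold grows. The concentrated gamma excess
  (shape 6, mean fixed by $f_b$ with a 2.5× margin over the floor) keeps
  under ~1% of pauses in the band, reproducing the threshold robustness of
  real data. This is an assumption, not an estimate: the real IS-duration
  distributions are not published.

Within an AS the mouse random-walks outside its nest cell (reflected into
the cage, mirrored out of the nest cell) emitting movement events in short
1 s-spaced bouts; feeding occupies 5 s slots with probability
`0.06 + 0.45·exp(−decay · t_from_onset)` (decay per minute, strain-specific)
and drinking has a 0.05 baseline with a 0.55 bump in the final
`drink_offset_width_s` (default 60 s) before offset. During ISs the animal
emits sparse movement events inside the nest cell only. Event times are
snapped to a 1 s grid — the discretization of a real acquisition system —
which also lets the per-second oracle match the parser exactly. Daily intake
totals are per-minute rates times total ingestion time, so per-event amounts
are constant per second of ingestion by construction (useful for testing
that intensity patterns carry no circadian signal when none is simulated).

`default_strain_library()` builds nocturnally biased AS-probability profiles
(Gaussian dark-phase bump; peak position, amplitude, width and baseline on
interleaved deterministic grids plus a small seeded jitter) verified to be
pairwise distinct (L2 > 0.05) and dark-dominant; ingestion rates and
locomotor speed also vary by strain so that the combined 99-D features carry
multimodal strain signal.

What the generator does **not** emulate: un-modeled behaviors (grooming,
rearing — real "other" time has structure ours lacks), drifting or multiple
home bases, device malfunction, between-day non-stationarity, body-weight
covariates, and pauses near the threshold (by design, except in adversarial
configurations built by hand). Passing tests therefore certify the
*algorithms* — exact parsing, conservation, recovery of planted structure —
not robustness to every failure mode of real hardware.

## Problem sizes and numerical conventions

The test suite runs simulated cohorts at desk scale, chosen to exercise the
study design while keeping the suite fast: the discrimination and
heritability checks use 16 strains × 6 mice × 12 days (1,152 MDs; the full
monitoring design records 12 days per animal), the parser-oracle equivalence
uses 100 MDs at 1 s resolution, and the smaller behavioral checks use 2–4
strains with 2–4 mice and days. Heritability parameter-recovery tests
compare against the *realized* variance fraction of the drawn strain
effects — with only 16 strain effects, the realized genetic variance sits
noticeably off its nominal value, and the nominal target would conflate
estimator error with draw noise.

Floating-point conventions: occupancy and budget vectors are validated to
sum to 1 within 1e-9; interval complements drop zero-length fragments;
eigenvalues below `max(d) · 1e-12` are treated as null space. All
randomness flows through explicit integer seeds via deterministic substream
derivation (a string-hashed seed below 2^31 per stage/trial/mouse-day), so
every analysis is exactly reproducible from a root seed.

## Known limitations

- Locomotion time depends on the 1 s episode-gap parameter; with sparsely
  sampled movement streams the locomotion share is a lower bound.
- The AS-duration and IS-duration distributions of the simulator are
  assumptions; only their means are pinned to the target AS fractions, and
  bin-edge effects give the realized per-bin AS fraction a small bias
  relative to the target (the renewal process draws durations from the bin
  where a state starts).
- Mouse-level classification accuracy benefits from the within-animal
  train/test split of the standard design: half of each animal's days are
  seen in training, so individual idiosyncrasies are learnable. This is a
  property of the design itself, shared with the original analyses, and is
  why the chance-level check in the tests permutes labels at the mouse-day
  level.
- The heritability estimator assumes a balanced design; unbalanced cohorts
  must be subsampled (the package does this per bootstrap trial) rather
  than fitted with unbalanced variance components.
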