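---
title: "Methods: from sparse phone data to relapse-window statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from sparse phone data to relapse-window statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenovis)
```

`phenovis` analyzes the two data streams a smartphone digital-phenotyping
study of schizophrenia produces — ordinal survey responses (active data)
and GPS pings (passive data) — and summarizes both inside clinically
meaningful windows: a control period versus the month preceding each
logged relapse. This vignette records the models, the tunable parameters
and their defaults, the numerical choices, and what the synthetic
generator does and does not emulate.

## Data model

Survey data are long-format rows `(patient, date, section, question,
response)` over five sections (mood, sleep, social, anxiety, psychosis),
each question on a small ordinal scale (default 0–3). A `survey_schema`
fixes section order, question order and legal levels; every downstream
vectorization uses schema order so results do not depend on input row
order. GPS data are `(patient, timestamp, latitude, longitude)` pings,
bucketed into local calendar days.

## Imputation

Real self-report streams are sparse and irregular; both imputation methods
work per patient on the daily grid from the first to the last observed
survey date.

**LOCF** fills every missing day of a question with the most recent
earlier observation. Leading missing days either copy the first
observation backwards (`backfill_first`, default) or are dropped
(`drop_date`). LOCF is idempotent and never alters an observed value.

**Chained-equations imputation** works per (patient, section) on the
dates × questions matrix: missing cells start at the column mode; then each
question in turn is regressed (OLS on the integer level codes) on the
section's other questions over its observed rows, and its missing cells are
redrawn as prediction plus a Gaussian residual draw; after `mice_iterations`
(default 5) sweeps the imputed cells are rounded to the nearest legal level
and clipped. A column with fewer than two observations falls back to mode
fill with a warning. The draw is deterministic given the seed. The linear
conditional with rounding is the simplest family that respects a short
ordinal grid; predictive-mean matching and cross-section modeling were
deliberately left out — the per-section variable set matches the
per-section MCA downstream. The pipeline consumes a single completed table,
so `mice_chains` defaults to 1; multiple chains are averaged cell-wise and
re-rounded.

On synthetic sections whose questions share a latent day effect, the
chained-equations method uses same-day cross-question information that LOCF
cannot see, and its masked-cell mean absolute error is correspondingly
lower (about 0.60 vs 1.08 level steps at 30% MCAR missingness in the
acceptance run; `scripts/acceptance.R` recomputes both numbers).

## Per-section MCA, trend, and eigengaps

Each section-date is one-hot coded into an indicator matrix $Z$ (dates ×
question-levels, row sums $Q$ = questions in the section; unused levels are
kept as zero columns so the layout is schema-determined). With $P = Z/N$,
row masses $r$, column masses $c$:

$$S = D_r^{-1/2}\,(P - r c^{\top})\,D_c^{-1/2}, \qquad S = U \Sigma V^{\top},$$

principal inertias $\lambda_k = \sigma_k^2$, row principal coordinates
$F = D_r^{-1/2} U \Sigma$. Components are kept up to
$\min(\text{rows}, \text{columns}) - 1$. Zero-mass columns carry no inertia
and are excluded from $S$. If all rows are identical, total inertia is
zero: the fit is flagged degenerate, scores and eigengaps are all zero
rather than an error, and everything downstream (flat trend, zero window
SDs, unflagged windows) follows consistently.

Two conventions make runs reproducible:

* **Sign.** SVD leaves each component's sign free. The sign is fixed so the
  component's correlation with the dates' mean raw response is
  non-negative (ties: the largest-magnitude loading is made positive), so
  "up" in a trend chart means higher reported levels.
* **Eigengaps on proportions.** The first and second eigengaps are
  $p_1 - p_2$ and $p_2 - p_3$ on inertia *proportions*
  $p_k = \lambda_k / \sum_j \lambda_j$, zero-padded below three components.
  Proportions make the diagnostic scale-free across sections with
  different question counts. The optional Benzécri correction
  (`fit_mca(..., benzecri = TRUE)`) re-weights proportions toward
  above-average inertias; it changes no scores.

The **MCA trend** is the date-indexed first-component score. A large first
eigengap indicates responses dominated by one consistent dimension. Note a
structural subtlety found while validating the generator: the relationship
between response variability and the first eigengap is monotone only from
the coherent regime upward. If responses are *too* uniform (every question
at the same level each day), the section degenerates into a single
categorical variable whose CA spectrum spreads symmetrically over level
dimensions, and the gap shrinks again. The package's Monte-Carlo tests
therefore probe the erratic direction — raising within-section question
noise lowers the mean first eigengap — which is the axis the diagnostic is
meant to detect.

## Date vectors, clustering ensembles, coassociation

Each date is summarized as an **aggregate vector** (AV: per-section means,
length = number of sections) or a **complete vector** (CV: schema-ordered
concatenation of all responses, length = total question count). Vectors are
used unstandardized by default (components already share the ordinal
scale); a z-score option exists.

The ensemble default is {k-means, Ward agglomerative} × k ∈ {2, 3, 4}
("predefined" clustering) plus silhouette-selected k-means ("natural"
clustering, argmax mean silhouette over k ∈ 2..`k_max`, ties to the
smallest k), each with 5 seeded restarts, run separately for AV and CV.
Euclidean distance throughout, matching the integer coding. Member seeds
are derived deterministically from the master seed. The **coassociation
matrix** entry $(i, j)$ is the fraction of member partitions co-clustering
dates $i$ and $j$ — symmetric, unit diagonal, entries in multiples of
$1/E$, invariant to relabeling within members. The package deliberately
stops at the matrix (the clinical view is the matrix heatmap itself); no
consensus partition is extracted from it.

## Passive summaries

Pings are projected to a planar frame by an equirectangular projection
about the patient's median coordinate — at city scale the distortion is
negligible and it keeps k-means in ordinary Euclidean space. Each ping is
dwell-weighted by the gap to the next ping, capped at `max_gap_min`
(default 60 min) so overnight recording gaps do not dominate; the final
(right-censored) ping takes its preceding gap, which keeps dwell fractions
exactly invariant when the ping rate is uniformly doubled. Candidate
locations come from k-means with k = min(`max_locations` = 6, occupied
~200 m grid cells); clusters whose centroids fall within `radius_m`
(default 200 m) of each other are merged (k-means happily splits one dwell
cloud; the merge undoes that), and clusters below 1% of total dwell are
dropped to an implicit "other". Locations are ranked by total dwell;
rank 1 is **home**, ties broken by earliest first visit. Daily summaries
assign each ping to its nearest location within `radius_m` (else "other"),
giving per-day dwell fractions that sum to one and
`home_time_pct = 100 ×` home fraction; days without pings are emitted as
blank (missing) rows so calendars show gaps honestly.

## Windows and anomaly flags

A "month" is a fixed 30-day window for determinism (real tables in this
field show n = 23–31 per window; a calendar-month mode was considered and
rejected as less reproducible; window length is a parameter). Each relapse
date $r$ yields a window $[r - 30, r)$; the control window is the earliest
30 clean days not overlapping any relapse window (overridable), truncated
at span edges with the truncation reflected in n. Summaries report n,
mean, and sample SD (ddof = 1; SD printed as 0 when n = 1, missing when
n = 0) of each section's trend per window. A section flags when
$\mathrm{sd}_{\text{relapse}} / \max(\mathrm{sd}_{\text{control}},
\varepsilon) \ge$ `ratio_threshold` (default 2, $\varepsilon = 10^{-6}$ so
a flat control trend with any relapse variability flags). The threshold is
an artifact default: the underlying clinical claim is qualitative
("markedly higher SD before relapse"), and the ratio is exposed alongside
the flag.

## Synthetic generator: what it emulates, and not

Per section and day, a latent Gaussian day effect $a_d \sim N(0,
\sigma_{\text{day}})$ is shared by the section's questions; each question
adds independent $N(0, \sigma_q)$ noise around the section mean, and the
sum is rounded to the nearest legal level. Inside each pre-relapse window
the day-effect SD is multiplied by `relapse_sd_inflation` (default 3) and
the mean shifted by `relapse_mean_shift` (default 0.3) — erratic, slightly
elevated responding. Responses are deleted MCAR at `missing_rate` (default
0.15). GPS pings are emitted `pings_per_day` (default 24) times daily, at
home with probability 0.6 (0.85 in pre-relapse windows) else at one of
three fixed satellite locations 2–4 km away, with ~20 m coordinate jitter.
One seed stream per (patient, data kind) makes survey and GPS draws
independently reproducible.

Default scale parameters: $\sigma_{\text{day}} = 0.6$ and $\sigma_q = 0.5$
on the 0–3 level scale. These were calibrated once, at design time, so the
control period behaves like a genuine null for the SD-ratio flag: with
much smaller day-level SDs, control-window trends become near-degenerate
(a handful of distinct values), window SD estimates turn heavy-tailed, and
the flag fires spuriously in ~20% of no-effect patients; at 0.6/0.5 the
null flag rate is ~5% while the inflation-3 detection rate stays at 100%.
Day-to-day movement of one ordinal step is also what self-report EMA data
plausibly look like.

The generator emulates *structure*, not clinical realism: no
autocorrelation in symptoms, no informative missingness (real
non-response is plausibly worst exactly when patients are unwell), no
weekday/weekend mobility rhythm, no multi-relapse interaction, uniform
ping cadence. Passing tests therefore demonstrate that the pipeline
recovers the signatures it targets when they are present and stays quiet
when they are absent — not that those signatures look exactly like real
patients' data.

## Numerical choices and scales

Eigenvalues below $10^{-12}$ are treated as zero (machine-level inertia).
Oracle comparisons in the test suite run at $10^{-8}$ on eigenvalues and
|row scores|, restricted to components with isolated eigenvalues (a tied
eigenvalue leaves the score basis undetermined, so a column-wise
comparison is meaningless there). Matrix CSVs are written at 15
significant digits and round-trip within $10^{-9}$. Monte-Carlo checks in
the default test run use 100 replicates for flag rates, home-time
recovery, and k-recovery, 50 for imputation MAE, 200 random designs for
the MCA oracle, and a 24-patient cohort (180 days) for the end-to-end
determinism check — sizes chosen to make the properties sharp while
keeping the default suite quick.

## Known limitations

* The significant-location step is a documented k-means surrogate, not a
  re-implementation of the GPS-statistics literature's inference; it is
  adequate for well-separated urban dwell clouds.
* Chained-equations imputation assumes linear level relations within a
  section and MCAR/MAR-style missingness; no Rubin pooling across chains.
* The control window is a policy choice (earliest clean 30 days), not a
  clinical definition; sensitivity to it should be explored via the
  `control_start` override.
* Reports are static HTML by design; the interactive portal this package's
  outputs could feed is out of scope.
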