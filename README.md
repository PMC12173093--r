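# phenovis

Analytics for smartphone **digital phenotyping** in serious mental illness,
built around the retrospective question clinicians actually ask: *did this
patient's recorded behavior change in the month before their relapse?*

Studies of schizophrenia with apps such as mindLAMP collect two data
streams: **active** data (short ordinal survey sections — mood, sleep,
social, anxiety, psychosis — answered on 0–3 scales, sparsely and
irregularly) and **passive** data (GPS pings). `phenovis` turns both into
per-day derived series and compares a control window against the 30 days
preceding each clinically logged relapse:

1. **Imputation** of missing survey responses, per patient and section, by
   last observation carried forward (LOCF) or chained-equations imputation
   (MICE-style: per-question linear conditionals on the integer level
   codes, iterated, rounded back to legal levels).
2. **Multiple correspondence analysis (MCA)** per survey section. With
   indicator matrix *Z* (dates × question levels), correspondence matrix
   *P = Z/N*, row/column masses *r, c*, the standardized residuals
   *S = D_r^{-1/2}(P − rcᵀ)D_c^{-1/2}* are decomposed by SVD; principal
   inertias are λ_k = σ_k², row principal coordinates *D_r^{-1/2}UΣ*. The
   first-component score per date is the **MCA trend**; the **eigengaps**
   p₁−p₂ and p₂−p₃ on inertia proportions diagnose how one-dimensional
   (consistent) a section's responses are.
3. **Date clustering ensembles** over per-date vectors — the aggregate
   vector AV (per-section means, length 5) and the complete vector CV (all
   responses, length = total question count) — with user-k ("predefined")
   k-means/Ward and silhouette-selected ("natural") k-means members. The
   ensemble is condensed into a **coassociation matrix**: entry (i, j) is
   the fraction of members placing dates i and j in the same cluster.
4. **Passive summaries**: significant locations from k-means over locally
   projected pings, dwell-weighted by capped inter-ping gaps; "home" is the
   top-dwell location; per-day **home-time %** and dwell fractions.
5. **Window statistics**: mean and sample SD of each section's MCA trend in
   the control window vs each pre-relapse window, with an SD-ratio anomaly
   flag (default ratio ≥ 2).
6. A **synthetic cohort generator** (latent Gaussian per section-day,
   discretized; MCAR missingness; GPS with elevated pre-relapse home-ping
   probability) so the whole pipeline is testable offline, plus static
   two-panel comparative HTML **reports**.

## Worked example

```r
library(phenovis)

cfg     <- synth_config(n_patients = 1, seed = 42)   # 180-day synthetic patient
patient <- generate_patient(cfg, 1)
# relapse logged on: 2022-02-08

complete <- impute_survey(patient$survey, cfg$schema,
                          imputation_config("mice", seed = 42))
mcas   <- fit_section_mcas(complete, cfg$schema)
trends <- lapply(mcas, mca_trend)

windows <- define_windows(patient$relapse_dates, range(complete$date))
summary <- summarize_windows(trends, windows)
flags   <- flag_anomalous_windows(summary, ratio_threshold = 2)
flags
#>   section   window    sd_ratio flagged
#> 1 mood      relapse-1     2.11 TRUE
#> 2 sleep     relapse-1     2.90 TRUE
#> 3 social    relapse-1     1.96 FALSE
#> 4 anxiety   relapse-1     3.50 TRUE
#> 5 psychosis relapse-1     3.65 TRUE
```

Four of five sections show a trend SD more than twice the control-window SD
in the month before the relapse — the generator's variance-inflation
signature, recovered by the pipeline. The passive stream confirms it:

```r
locs  <- find_significant_locations(patient$gps, seed = 42)
daily <- daily_summaries(patient$gps, locs)
#> mean home time: control 59.9% vs pre-relapse month 85.5%
```

End to end over a cohort (reads a directory written by
`generate_cohort()`, writes per-patient CSVs, window flags, and two-panel
HTML reports):

```r
generate_cohort(synth_config(seed = 0), "data")
run_pipeline(pipeline_config("data", "out",
                             imputation = imputation_config("mice")))
```

or from a shell: `inst/cli/phenovis simulate --out data && inst/cli/phenovis run --data data --out out`.

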