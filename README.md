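# muscleBOLD

Quantitative analysis of blood oxygen level-dependent (BOLD) MRI of
lower-extremity skeletal muscle under a cuff-occlusion / reactive-hyperemia
paradigm, for researchers studying microvascular muscle oxygenation
(exercise physiology, peripheral artery disease, training response).

A 15-minute T2\*-weighted acquisition (5 min baseline, 5 min thigh-cuff
occlusion, 5 min hyperemia; TR = 3 s) yields, for each calf muscle VOI
(gastrocnemius, soleus, anterior tibialis, peroneus longus), a signal time
course that the package normalises to percent change from baseline,

SI%(t) = 100 · (SI(t) − SI̅_base) / SI̅_base,

and summarises with four dynamic indices:

| index | definition |
|---|---|
| **PHV** (%) | peak hyperemic value — highest 3-s average after cuff deflation |
| **TTP** (s) | time from deflation to the peak |
| **MIV** (%) | minimum ischemic value during occlusion |
| **TTR** (s) | time from deflation to return to the baseline level |

On top of the per-subject indices the package provides the cohort layer:
test–retest coefficients of variation (100·SD/|mean|) with paired visit
comparisons, group-wise and muscle-wise one-way ANOVA with
D'Agostino–Pearson normality screening and Tukey HSD post-hocs, and Pearson
correlations between PHV and maximal vertical/broad jump. A ground-truthed
synthetic module (response curves, full 4D NIfTI phantoms, whole cohorts)
validates every stage without scanner data.

## Worked example

```r
library(muscleBOLD)
tm <- protocol_timing()                     # 0/300/600/900 s, TR 3 s
ph <- simulate_phantom(phantom_spec(noise_sd = 2), seed = 1)

raw <- extract_voi_timecourse(ph$series, ph$mask, "soleus")
ntc <- percent_change_normalize(raw, tm)
compute_indices(ntc, tm)
#> <bold_indices> soleus: PHV 12.9%, TTP 22.5 s, MIV -12.3%, TTR 133.2 s
```

The phantom's soleus truth is PHV 12.9 %, TTP 21 s, MIV −12.4 %,
TTR 134.1 s: with 2 units of scanner noise on a baseline of 400 the
pipeline recovers the amplitudes to ~0.1 % and the times to within one TR
(timing indices are quantised by the 3-s frame grid).

Cohort level, on a simulated study population (12 linemen, 11
backs/receivers, 10 twice-scanned controls):

```r
rec <- simulate_cohort(cohort_spec(), seed = 7)
jump_correlation(rec, "gastrocnemius", "vertical")
#>          muscle functional_measure parameter     r        p  n n_excluded
#> 1 gastrocnemius           vertical       phv 0.602 0.000212 33          0
```

i.e. the generated gastrocnemius PHV–jump association (population
correlation 0.56) is estimated at r = 0.60 in this draw.
`repeatability_table(rec)` gives the per-muscle visit-1/visit-2 means, CVs
and paired p-values; `group_muscle_anova(rec, "phv")` the omnibus and
Tukey comparisons; `run_subject()` / `run_cohort()` write the same results
as CSV + JSON from a YAML config.

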