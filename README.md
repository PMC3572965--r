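# wmlpatterns

Spatial patterns of cerebral white-matter lesions (WML) and the risk of
progressing to mild cognitive impairment (MCI) or dementia.

In community-dwelling elderly cohorts, the *amount* of white-matter
damage visible on MRI predicts cognitive decline only weakly; its
*location* may matter as much. `wmlpatterns` implements a bottom-up
pipeline that discovers prognostic spatial WML patterns from regional
lesion volumetry and then quantifies their hazard, together with a
synthetic longitudinal cohort generator so that the whole analysis is
reproducible and testable without access to the original study data.

The pipeline, in the order the analysis scripts run it:

1. **Descriptors** — from the frontal, parietal, temporal and occipital
   lesion volumes (ml): the total volume and the four relative regional
   volumes, `WMLr = 100 × region / total` (%).
2. **Pattern search** — an exhaustive binary decision tree over the five
   descriptors. At each node every descriptor/threshold pair (thresholds
   are the midpoints between successive distinct observed values) is
   scored by the weighted Gini impurity of its children,
   `n_L/n (1 − Σ p_i²)_L + n_R/n (1 − Σ p_i²)_R`, and the minimiser is
   retained; growth stops when a child would hold fewer than 6 subjects.
   Ten such trees are grown by 10-fold cross-validation and a depth-2
   **consensus tree** keeps, at the root and at the second level of the
   `≥` branch, the descriptor used by a strict majority of fold trees,
   with its threshold set to the modal fold value. The consensus defines
   pattern 1 (low total load), pattern 2 (heavy load, spared temporal
   region) and pattern 3 (heavy load with temporal involvement — the
   at-risk group).
3. **Survival analysis** — delayed-entry (left-truncated) Cox
   proportional-hazards models on the age timescale, with onset dated
   halfway between the last cognitively normal visit and the diagnosing
   visit, deaths censored at the age of death, and five nested covariate
   sets up to the fully adjusted model (sex, education, vascular
   history, hypertension, APOE ε4, depressive symptomatology, total
   brain volume, hippocampal volume, brain atrophy, silent brain
   infarcts).

The synthetic generator emulates the statistical structure of an
ESPRIT-like MRI sub-cohort: 426 subjects aged 65–79, log-normal total
WML volume (mean 1.79 ml, SD 3.56 ml) with an age trend, zero-inflated
regional shares, a planted three-pattern geography (total ≥ 1.587 ml,
temporal WMLr ≥ 0.65 %), a pattern-3 log hazard ratio of log(2.28) on an
age-graded baseline hazard, scheduled visits at years 0/2/4/7 with
visit-detected (interval-censored) onsets, and age-graded death and
loss-to-follow-up censoring.

## Worked example

```r
library(wmlpatterns)

cohort  <- generate_cohort(cohort_config(), seed = 1)
report  <- run_pipeline(cohort, k = 10, min_leaf = 6, seed = 1,
                        models = integer(0))
print(report)
```

```
<pipeline_report> n = 426 subjects, 104 incident MCI/dementia (seed 1)
<consensus_tree> 10 fold trees, min_leaf = 6
  root:   total_wml < 1.419 (pattern 1) vs >= (patterns 2/3)
  second: temporal_wmlr < 2.665 (pattern 2) vs >= (pattern 3)
  pattern counts: pattern1=288, pattern2=65, pattern3=73
  at-risk (pattern 3) vs incident MCI/dementia: sens 37.5%, spec 89.4%, PPV 53.4%, NPV 81.6%
  incidence (all): 104 events / 2218.0 person-years = 46.9 per 1000 py
  incidence (mci): 97 events / 2218.0 person-years = 43.7 per 1000 py
  incidence (dementia): 7 events / 2218.0 person-years = 3.2 per 1000 py
```

On this cohort the consensus recovered the planted descriptor pair
(total volume, then temporal share); the recovered cuts (1.419 ml,
2.67 %) sit near the planted discontinuities (1.587 ml, 0.65 % — the
second threshold is overestimated, a bias the vignette analyses). The
2×2 line reads: of the 104 subjects who progressed, 37.5% carried the
at-risk pattern at baseline; of those who stayed healthy, 89.4% did not.
Fitting the fully adjusted Cox model to the same records
(`cox_delayed_entry(records, model = 5)`) gives a pattern 3 vs pattern 1
hazard ratio of 3.45 (95% CI 2.22–5.38) at these resubstitution cuts,
and ~2.3 when patterns are assigned at the true thresholds.

The numbered drivers under `analysis/` run the same stages against files
on disk (`01_simulate_cohort.R` → `04_recovery_study.R`), writing their
tables under `results/`.

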