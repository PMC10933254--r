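# copdengage

Engagement phenotyping and short-horizon exacerbation risk modelling
for COPD self-management diaries.

People with COPD keep daily symptom diaries (a 1–4 self-assessed score)
and medication records in self-management apps. Machine-learning models
can predict exacerbations — acute worsenings treated with a home
"rescue pack" of oral steroids and antibiotics — a few days ahead from
those diaries, but only as well as users keep reporting. This package
implements the full quantitative pipeline for studying that dependence:

* **Diary model** — CSV ingestion/validation and exacerbation
  identification from rescue-pack courses (onset = first course day;
  courses > 10 days excluded; overlapping courses merged; entries made
  > 10 days late flagged retrospective).
* **Engagement phenotyping** — per-event usage fractions over the 70
  days pre/post onset and the 21 days pre; classes *frequent*
  (fraction ≥ 0.66), *intermediate*, *infrequent* (< 0.33);
  *engaged-near-exacerbation* transitions; self-report quality labels
  (fixed reporting / reporting with signal); post-event disengagement.
* **Synthetic data** — (a) a cohort generator whose defaults encode the
  studied world (243 users, 60.3% frequent, transition rates
  21.8%/14.4%, SABA usage peaking at onset with scores peaking 3 days
  later); (b) day-offset-conditioned empirical group profiles and a
  simulator producing 1000 exacerbation-aligned series per engagement
  group.
* **Features** — per-day prediction instances from day −55 to +70 with
  a binary "onset within 3 days" label and trailing-window (4/8/15-day)
  mean, SD, count, min, max of registered scores; missing stays
  missing.
* **Model & evaluation** — an in-package histogram gradient-boosted
  tree learner (no external boosting library required), 75–25
  series-level split, series-grouped 5-fold CV with budgeted random
  hyperparameter search, and per-group AUROC / average precision with
  series-bootstrap 95% CIs, plus a median-imputed logistic baseline.
* **Descriptive analyses** — first-vs-subsequent event-aligned
  profiles, pooled-score chi-square comparison, SABA/score peak lag,
  GOLD 2022 grouping and the engagement × GOLD cross-tab.

## Worked example

```r
library(copdengage)

co   <- generate_cohort(cohort_config(n_users = 60, seed = 7))
ev   <- identify_exacerbations(co$medications)
prof <- build_engagement_profiles(ev, co$symptoms)
engagement_summary(prof)
#> Engagement summary over 173 exacerbation events
#>   infrequent     28 (16.2%)
#>   intermediate   45 (26.0%)
#>   frequent      100 (57.8%)
#>   transitional (engaged near exacerbation): 21.9% of non-frequent
#>   post-event disengagement flag: 17.3% of events
```

Most events here come from frequent reporters (at 60 users the realised
shares sit a few points from the configured 18.2/21.5/60.3% mix), and
about a fifth of the non-frequent events show the transition to higher
engagement in the 21 days before onset.

The full study — phenotype, simulate 1000 series per group, featurise,
tune, train, stratified evaluation — runs from one config:

```r
res <- run_study(study_config(budget = 10, seed = 20240312), out_dir = "study_out")
res$evaluation[, .(group, auroc, average_precision)]
```

AUROC and average precision rise with 70-day engagement
(infrequent-consistent → intermediate-consistent → frequent), and the
engaged-near-exacerbation strata sit far above their consistent
counterparts, close to the frequent group: transitional engagement,
not blanket engagement, is what protects model performance. The same
five-strata report is written to `study_out/evaluation_report.csv`
together with the engagement summary, simulator profiles, descriptive
outputs and a run log.

A command-line driver is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "copd-engage", package = "copdengage"))')" \
    run-all --config study.yaml --out study_out
```

## Documentation

See the methods vignette
(`vignettes/engagement-and-risk-modelling.Rmd`) for the model,
generator assumptions, numerical choices and limitations.
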