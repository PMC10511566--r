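# cognorm

Regression-based normative data for an eight-test neuropsychological
battery (SDMT, category/letter fluency, the three Stroop subtests,
trail making A/B), built the way modern normative studies build them:
a screened healthy cohort, Bayesian normative models per test,
predictive-distribution z-scores, and a lookup-table calculator.

The package is aimed at clinicians and methodologists who need
demographically adjusted scores — *given this patient's age,
education, gender and administration language, how unusual is this raw
score?* — and at anyone who wants to study the norming pipeline itself
under a known ground truth.

## The model

For each test, the (log-transformed, for the timed trail-making tests)
raw score is modelled as

    y_i = beta_0 + f(age_i) + g(edu_i) + beta_F * female_i
          + beta_L[lang_i] + eps_i,    eps_i ~ N(0, sigma^2)

with `f` and `g` penalized cubic B-spline smooths (second-order
random-walk penalty; the linear candidate model replaces them with
straight lines), English the reference language, flat priors on
coefficients and weakly informative priors on scales. Posterior
sampling is a blocked Gibbs sweep with collapsed slice updates of the
smoothness scales; candidate models ({linear, additive} x {all four
predictors, drop one at a time}) are compared by PSIS-LOO with a
paired 95% CI rule. A raw score maps to

    z = (t(y) - mu_hat(x)) / sd_pred(x),   percentile = 100 * Phi(z),

sign-flipped for tests where lower raw scores are better, with
qualitative bands (markedly below / below / normal / above) at
z = -2, -1, +1.

Real normative registries are controlled-access, so the package ships
a synthetic cohort generator moment-matched to the published
demographic marginals (mean age 46.99, SD 14.61 on [18, 86]; education
14.66, SD 3.27; 60.5% female; ten languages at published frequencies)
with the published gender/language effects planted as ground truth.
All calibration and recovery claims are tested against that truth.

## Worked example

The numbered scripts under `analysis/` run the whole study:

```sh
Rscript analysis/01_simulate_cohort.R     # cohort of 3267, violations planted
Rscript analysis/02_screen_cohort.R       # screening chain -> n = 2713
Rscript analysis/03_model_selection.R     # 10-model ladder per test
Rscript analysis/04_fit_selected_models.R # selected fits + diagnostics
Rscript analysis/05_norm_tables_effects.R # table norms, effect summaries
Rscript analysis/06_normative_calculator.R# lookup table + scoring
```

Stage 2 prints the attrition chain (baseline 102 removed, non-native
158, uncorrected vision/hearing 28, missing fields 53, HADS 136,
MMSE 77; 2713 of 3267 remain). Stage 3 ranks the ten candidates per
test; on this cohort the full additive model wins SDMT outright
(LOO-IC 20256.3, the linear full model trails by 50.4 with a CI
excluding zero) and the gender-dropped additive model ranks best for
SWRT, matching what is expected when the planted SWRT gender effect
(0.59 points) is negligible against a residual SD of 15. Stage 4
reports max split-R̂ of 1.005/1.007 (both under the 1.01 bar) and one
Pareto k̂ ≥ 0.5 observation per fit. Stage 5 recovers the planted
effects, e.g.

    SDMT gender effect: M = 2.43, 95% HDI [1.71, 3.17]   (planted 2.78)
    SWRT PL   M =  -8.05 [-11.12,  -4.36]                (planted -7.80)
    SWRT ES   M =   9.42 [  7.50,  11.53]                (planted  7.28)

and stage 6 scores raw results through the lookup table:

    SWRT 77, Polish speaker, f/34y/13y edu    z = -0.85, percentile 19.8, normal (green)
    SWRT 77, English speaker, f/34y/13y edu   z = -1.39, percentile  8.2, below (orange)
    SWRT 85 (77 shifted by fitted offset), EN z = -0.85, percentile 19.7, normal (green)

The same raw score is "normal" for a Polish speaker and "below" for an
English speaker, and shifting the English score by the fitted Polish
offset reproduces the Polish z — the language-adjustment logic the
norms exist to provide.

Interactively:

```r
library(cognorm)
cohort <- sample_scores(sample_demographics(cohort_config(), 3000, seed = 1),
                        list(default_truth("SDMT")), seed = 2)
fit <- fit_normative_model(model_spec("SDMT", form = "GAM"), cohort)
score_raw(fit, "SDMT", age = 48, edu_years = 14, sex = "f",
          lang = "EN", raw = 60)
```

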