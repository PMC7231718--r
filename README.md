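# gbscure

Bayesian promotion-time cure-rate survival modelling with a generalized
Birnbaum–Saunders event-time law.

## The problem

In long-running cancer registries a large share of patients never die of
their disease: the Kaplan–Meier curve flattens into a plateau instead of
falling to zero.  Standard survival models, which assume everyone
eventually experiences the event, fit such data badly and conflate two
different questions — *who is cured* and *how fast do the non-cured die*.
Cure-rate models separate them.  `gbscure` is written for biostatisticians
and epidemiologists analysing heavily censored cohorts of this kind
(the motivating setting is a breast-cancer registry cohort of 3184 women
followed up to 23 years with 83% censoring), and for methodologists who
want a fully reproducible, testable implementation of the model on
synthetic data.

## The model

Each subject carries a latent number \(M\) of competing causes
("promoted" tumour cells), with

\[ M \sim \mathrm{Geometric}(\theta), \qquad P(M=m) = \theta(1-\theta)^m,
   \quad m = 0, 1, 2, \dots \]

A subject with \(M = 0\) is **cured**; \(\theta\) is simultaneously the
geometric parameter and the cure fraction.  Each latent cause carries an
event time from a generalized Birnbaum–Saunders (GBS) distribution with
shape \(\alpha\), scale \(\beta\) and power parameter \(\nu\),

\[ F(t) = \Phi\!\left(\tfrac{1}{\alpha}\left[(t/\beta)^{\nu} -
   (\beta/t)^{\nu}\right]\right), \]

which reduces to the classical Birnbaum–Saunders law at \(\nu = 1/2\).
The observable survival function is the probability generating function of
\(M\) at the latent survival \(S(t)\):

\[ S_p(t) = \frac{\theta}{1 - (1-\theta)\,S(t)}, \]

decreasing from 1 to the plateau \(\theta\).  Covariates act on the cure
fraction through a logit link, \(\theta_i = \mathrm{logit}^{-1}(x_i'\beta)\),
so \(e^{\beta_j}\) is a **cure odds ratio**.  Inference is Bayesian:
component-wise adaptive random-walk Metropolis with weakly-informative
priors, summarised by posterior means, quartiles and 95% highest posterior
density (HPD) intervals; an effect is flagged when its HPD interval
excludes zero.

## Worked example

Generate a registry-like synthetic cohort (3184 subjects, published
covariate marginals and cure-odds coefficients, ~83% administrative
censoring), look at the descriptive layer, then fit the cure model:

```r
library(gbscure)

cohort <- generate_cohort(cohort_config(), seed = 1)
km <- km_fit(cohort$time, cohort$event)
km
#> Kaplan-Meier curve: n = 3184, events = 557 (82.5% censored)
#> follow-up 0.231-23, final survival 0.453

landmark_survival(cohort, times = c(1, 5, 10, 15, 20))
#>     group time  survival
#> 1 overall    1 0.8189232
#> 2 overall    5 0.5102342
#> 3 overall   10 0.4665246
#> 4 overall   15 0.4582172
#> 5 overall   20 0.4525602

restricted_mean(km)
#> Restricted mean survival time (horizon 23): 11.689 (se 0.378, 95% CI 10.948-12.430)
```

The survival curve flattens near 0.45 after year 10 — the cure plateau
(the generator's cohort-average cure fraction is 0.46).  Now the model:

```r
fit <- gbscure(
  survival::Surv(time, event) ~ age_group + surgery + tumor_size + nodes +
    stage + grade + lvi + er + pr,
  data = cohort,
  control = gbscure_control(n_iter = 6000, burn_in = 2000, thin = 4, seed = 2))
summary(fit)
#> Posterior summary (18 parameters, 95% HPD)
#>
#>                   mean    sd    p25    p50    p75 exp_mean hpd_low hpd_high signif
#> (Intercept)     -1.718 0.266 -1.881 -1.702 -1.534    0.179  -2.225   -1.191      *
#> age_group<40     0.439 0.165  0.324  0.435  0.556    1.551   0.092    0.733      *
#> ...
#> lvipos          -1.137 0.107 -1.209 -1.137 -1.059    0.321  -1.330   -0.928      *
#> ...
#> alpha            0.930 0.185  0.817  0.895  0.975    2.534   0.659    1.397
#> beta_scale       2.653 0.203  2.506  2.641  2.786   14.191   2.275    3.035
#> nu               0.498 0.067  0.457  0.489  0.518    1.646   0.390    0.658
```

Reading the `lvipos` row: subjects with lymphovascular invasion have cure
odds `exp_mean = 0.321` times those without (the generating value was
0.320, i.e. a coefficient of −1.139), and the HPD interval (−1.330,
−0.928) excludes zero, so the effect is flagged.  `alpha`, `beta_scale`
and `nu` describe the event-time law of the non-cured; `nu ≈ 0.5` says the
classical Birnbaum–Saunders sub-model would suffice here (it is the
generating value).  Posterior survival curves for individual covariate
profiles come from `predict(fit, newdata, times, type = "survival")`, and
`plot(fit)` overlays the fitted marginal curve on the Kaplan–Meier
estimate.

The whole pipeline — descriptive table, landmark table, fit, posterior
summary TSV, draws CSV, run log — is one call:

```r
run_cure_analysis(config = cohort_config(), out_dir = "analysis")
```

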