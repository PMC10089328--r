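# geociaf

Bayesian geo-additive modelling of the Composite Index of Anthropometric
Failure (CIAF) in under-five children.

## What it does, and for whom

Child undernutrition is usually tracked through three z-score indices —
height-for-age (stunting), weight-for-height (wasting) and weight-for-age
(underweight) — that capture different biological processes and co-occur.
The CIAF aggregates them: a child is in anthropometric failure when *any*
of the three z-scores falls strictly below −2 SD.  `geociaf` is for
epidemiologists and biostatisticians who want to (1) classify children
into the CIAF groups and estimate prevalence, and (2) model the spatial
and socio-demographic determinants of the binary CIAF outcome across
administrative regions.

The core model is a structured additive (geo-additive) logistic
regression.  For child *i* in region *s*:

```
logit P(y_is = 1) = v_i' β  +  Σ_r f_r(x_ir)  +  f_str(s)  +  f_unstr(s)
```

* `v_i' β` — linear fixed effects of dummy-coded categorical covariates,
  diffuse priors;
* `f_r` — P-spline smooths of continuous covariates (cubic B-splines,
  20 segments, second-order random-walk prior with variance `τ²`);
* `f_str` — spatially structured region effects with an intrinsic
  Gaussian Markov random field (GMRF) prior on the region adjacency
  graph: conditional on its neighbours a region's effect is
  `N(neighbour mean, τ²_str / N_s)`;
* `f_unstr` — i.i.d. Gaussian region heterogeneity;
* every variance has an `IG(a = 0.001, b = 0.001)` hyperprior.

Posterior inference is a Gibbs sampler with Polya-Gamma data augmentation
(exact PG(1, z) rejection sampler in C++; all full conditionals Gaussian
or inverse-gamma; chains bit-reproducible under a seed).  Nested models
M0 (linear only) → M1 (+ smooths) → M2 (+ spatial) → M3 (full) are
compared by DIC with the plug-in effective-parameter count
`pD = Dbar − Dhat`.

Because the survey microdata this model targets are access-controlled, a
first-class synthetic-data module generates survey-like records on a
lattice region graph with known ground truth, and the test suite
validates the whole pipeline by parameter recovery.

## Worked example

```r
library(geociaf)

graph <- make_lattice_graph(3, 4)                 # 12-region rook lattice
dat <- simulate_ciaf_data(2000, graph,
                          mix = default_covariate_mix()[c("gender",
                                                          "diarrhoea")],
                          seed = 42)
spec <- star_spec("outcome", fixed = c("gender", "diarrhoea"),
                  smooth = list(child_age = smooth_term()),
                  spatial = spatial_term("region"))
fit <- star_fit(spec, dat, graph, chain_config(1500, 500, 2, seed = 1))

odds_ratio_table(fit)
#>            term  or_mean   cri_low cri_high significant
#> 1   gender:male 1.170612 0.9783806 1.411709       FALSE
#> 2 diarrhoea:yes 1.378769 1.0486213 1.741236        TRUE

variance_summary(fit)
#>      component        mean         sd      cri_low  cri_high
#> 1 s(child_age) 0.006430577 0.01115438 0.0005171838 0.0283513
#> 2   Structured 0.373133490 0.28053396 0.0880903891 1.0264279
#> 3 Unstructured 0.032014328 0.05421820 0.0008467595 0.1760224

head(spatial_significance(fit), 4)
#>   region mean_logodds     cri_low   cri_high code
#> 1    R01    0.8460480  0.52141783  1.1576511    1
#> 2    R02    0.2138288 -0.02983768  0.4861875    0
#> 3    R03   -0.0470278 -0.31819170  0.2073062    0
#> 4    R04   -0.8301784 -1.18214976 -0.4880669   -1

compute_dic(fit)
#> DIC 2609.70  (pD 16.62, mean deviance 2593.08, plug-in 2576.46)
```

Reading the output: the simulated truth includes a diarrhoea effect
(odds ratio 1.256) and a structured spatial field with variance 0.3 — the
fit flags diarrhoea as significant (95% CrI excludes 1), estimates the
structured variance at 0.37, and codes regions `+1 / 0 / −1` according to
whether their spatial log-odds interval lies above, across, or below
zero.  The smooth-curve summary is `smooth_effect_curve(fit, "child_age")`
(posterior mean and pointwise 95% band on the log-odds scale).

CIAF classification works directly on z-score tables:

```r
z <- simulate_zscores(5000, target_prevalence = 0.413, seed = 1)
ciaf_prevalence_table(z)[1:2, -5]
#>       status prevalence    ci_low   ci_high
#> 1       CIAF  0.4128826 0.3992342 0.4265310
#> 2 No failure  0.5871174 0.5734690 0.6007658
```

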