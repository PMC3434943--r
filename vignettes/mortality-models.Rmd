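---
title: "Modelling diet- and mating-dependent senescence in cricket cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling diet- and mating-dependent senescence in cricket cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mortsen)
```

## The scientific problem

Laboratory senescence experiments on insects typically follow every animal
in a factorial design (here 2 sexes x 2 diets x 2 mating treatments) from
adult eclosion (day 0) to death, recording the adult lifespan in days, and
for males the nightly calling effort (seconds of advertisement call per
15-hour recording window) every few days. Two questions drive the
analysis:

1. **Actuarial senescence.** How do diet and mating status shift the level
   and the age-dependence of mortality? This is asked of the hazard, not
   of mean lifespan: the instantaneous mortality rate \(\mu(x)\) at adult
   age \(x\) separates a *baseline* component from a *rate of ageing*.
2. **Reproductive effort.** How does male calling effort change with age,
   and does diet or mating alter that trajectory — allowing for the fact
   that short-lived males drop out of the observed population (selective
   disappearance)?

`mortsen` implements both analyses end to end, together with a synthetic
cohort generator that emulates the study design, so the complete pipeline
runs and is tested without any external data.

## Mortality models

Six hazard families are available through `hazard_spec()`, in the
parameterizations standard in demographic analyses of ageing:

| family             | hazard \(\mu(x)\)                                                      |
|--------------------|------------------------------------------------------------------------|
| constant           | \(\alpha\)                                                              |
| gompertz           | \(\alpha e^{\beta x}\)                                                  |
| gompertz_makeham   | \(c + \alpha e^{\beta x}\)                                              |
| logistic           | \(\alpha e^{\beta x}\,/\,[1 + (s\alpha/\beta)(e^{\beta x}-1)]\)         |
| logistic_makeham   | logistic \(+\;c\)                                                       |
| weibull            | \(a b x^{b-1}\)                                                         |

\(\alpha\) (day\(^{-1}\)) is the hazard at adult age 0, \(\beta\)
(day\(^{-1}\)) the exponential rate at which hazard rises with age,
\(c \ge 0\) an age-independent (Makeham) component, and \(s \ge 0\) the
late-age deceleration of the logistic family (\(s \to 0\) recovers
Gompertz). The constant family is the "no senescence" reference. Survival,
density, quantiles and random variates all derive from the closed-form
cumulative hazard; the Makeham quantiles use bracketed root-finding.

Because no closed form is printed for the non-Gompertz families in the
source literature for this design, the forms above are a design choice:
they are the canonical ones in the Pletcher/WinModest tradition that the
five-family comparison comes from, and each nests Gompertz in the
appropriate limit, which the test suite checks.

### Numerical choices

* All likelihood work happens on the **log working scale**
  (\(\log\alpha\), \(\log\beta\), ...): parameters stay positive, and
  treatment effects become additive — i.e. multiplicative on the hazard
  scale.
* \(e^{\beta x}-1\) is computed with `expm1`, and \(\beta < 10^{-10}\) is
  routed to the exact constant-hazard limit, so the Gompertz-to-constant
  boundary is continuous rather than a numerical cliff.
* Death times are treated as exact continuous ages even though survival is
  checked daily in this kind of experiment; the generator's
  `daily_rounding` flag (ceiling to whole days) lets a user measure the
  discretization bias this induces, which is negligible at these hazards.

## Treatment-structured maximum likelihood

`fit_mortality()` maximizes \(\sum_i \log \mu(t_i) + \log S(t_i)\) over
cohorts where diet, mating, and their interaction may act on \(\alpha\)
and/or \(\beta\) (`model_structure()`, hierarchical marginality enforced;
baseline levels diet C and mated). Every animal is followed to death, so
there is no censoring machinery. Optimization runs from heuristic starting
values (a profile solution for \(\alpha\) on a small \(\beta\) grid) plus
deterministically jittered restarts; Gompertz and constant families use an
analytic gradient, the others a simplex stage with a numeric-gradient
polish. Cells referenced by a structure must contain at least two deaths —
a hard data error, never silent dropping.

Confidence intervals default to **profile likelihood** (the
\(\chi^2_1\) 95% cutoff on the working scale, back-transformed), with Wald
intervals on the log scale as the fallback when a profile bound cannot be
bracketed (a warning is raised) or on request. At the cohort sizes used
here the two differ by well under 5%; the profile version is the default
because it respects the positivity constraint and the asymmetry of the
small-\(\alpha\) sampling distribution.

`run_battery()` fits all 25 hierarchical Gompertz structures plus the
constant-hazard model and ranks them by AIC (\(2k - 2\ell\)), with
\(\Delta\)AIC and Akaike weights
\(w_i = e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}\); non-converged fits are
excluded from the weight normalization, with a warning, rather than
failing the battery. AIC rather than AICc is the default to match standard
practice in this literature; AICc sits behind a flag. Sexes are analysed
in separate batteries; `sex_lrt()` supplies the pooled-versus-stratified
likelihood-ratio test (twice the log-likelihood difference against
\(\chi^2_8\)) that justifies the stratification.

## Lifespan summaries

`lifespan_table()` reports, per treatment group, the sample median with a
percentile bootstrap 95% CI (resampling within group; 5000 replicates by
default) and "maximum lifespan" defined as the median of the
longest-lived 10%. Two conventions were open and are fixed here
(configurably): the top decile holds \(\lceil n/10 \rceil\) animals, and
the bootstrap interval is the percentile flavour — the simplest choice
consistent with reporting medians.

## The calling-effort mixed model

Nightly calling effort is modelled as Gaussian with a random intercept per
male:

\[ y_{ij} = \mathbf{x}_{ij}^\top \boldsymbol\beta + u_i + e_{ij}, \qquad
   u_i \sim N(0, \sigma_u^2),\; e_{ij} \sim N(0, \sigma_e^2). \]

The fixed-effect vocabulary covers diet, mating, age, age², lifespan,
lifespan² and their products; including each male's own lifespan and its
square lets the within-individual age trajectory be separated from
selective disappearance. The random intercept is also the device that
absorbs within-individual temporal autocorrelation; no further
autocorrelation structure is modelled, and the random part is
intercept-only (the best-fit coefficient table this design mirrors implies
no random slopes).

The fitting engine (`fit_lmm()`) is implemented in this package: for a
fixed variance ratio \(\theta = \sigma_u^2/\sigma_e^2\) the fixed effects
and \(\sigma_e^2\) have closed-form GLS solutions via the Sherman–Morrison
form of \((I + \theta J)^{-1}\), leaving a one-dimensional maximization
over \(\log\theta\). ML (not REML) is the default so that AIC is
comparable across fixed-effect structures; REML is available behind a flag
that warns against AIC use. A \(\theta\) optimum at 0 is valid (ordinary
regression) and flagged. The test suite verifies the engine against a
brute-force maximization of the full marginal Gaussian likelihood on tiny
datasets and against an independent mixed-model implementation on larger
ones.

`compare_calling_models()` ranks candidate fixed-effect term lists with
the same AIC/weight arithmetic as the mortality battery.

## The synthetic-data generator

`experiment_config()` defaults *are* the study conditions: per-cell sample
sizes (males 82/76/72/70, females 71/76/61/67 for CV/CM/PV/PM), per-cell
Gompertz parameters equal to the published estimates, diet compositions
(protein:carbohydrate 9.33:74.66 for diet C and 42:42 for diet P, both
84% with cellulose filler), and calling observations from age 4 days,
every 5 days, strictly before death. Death times are inverse-CDF draws;
calling values come from the mixed model above with each male's own
generated lifespan on the right-hand side, reproducing the
selective-disappearance structure.

Two generator quantities are not printed anywhere and are documented
stand-ins: the calling intercept (0 s — only contrasts are specified by
the design) and the variance components (\(\sigma_u = 1500\) s,
\(\sigma_e = 3000\) s, the order of nightly calling variability in this
literature). Fixed-effect recovery is invariant to all three, which the
recovery tests demonstrate. The master seed spawns independent
sub-streams (deaths, intercepts, residuals, morphometrics), so switching
one component off does not shift another's draws. Negative simulated
calling values are kept unless `clip_calling` is set, because the fitted
model is linear-Gaussian; clipping is a realism option, not the default.

What the generator does *not* emulate: egg laying and fecundity, mass
trajectories, recording-hardware artefacts, non-Gaussian calling
distributions (real calling is zero-inflated and bounded), and any frailty
beyond the random intercept. Passing tests therefore show that the
estimators recover the generating process of this design faithfully — not
that real cricket data satisfy the model's assumptions.

## Problem sizes used in the checks

The test-suite and acceptance-script problem sizes are the package's own
choices, large enough that Monte-Carlo error is far below each assertion's
tolerance: 200,000 draws for median checks (MC error of the median
\(\approx 0.07\) d), 500,000 deaths for parameter-recovery refits
(relative error a few tenths of a percent), 50,000 males for
calling-model recovery (SE of the diet:age coefficient \(\approx 3\)
s/day against a \(\pm 10\) assertion), 200 replicates per treatment cell
at \(n = 10^4\) for profile-CI coverage (pooled across cells per
parameter), and 500 null replicates for LRT calibration. Qualitative
battery properties run on 20 generator seeds at the design's real sample
sizes, where model selection is genuinely noisy; the assertions there are
frequencies computed once from that simulation design, not certainties.

## Known limitations

* No censoring: cohorts must be followed to death, as in this design.
* No frailty/heterogeneity models and no multimodel parameter averaging.
* The likelihood-ratio test between the Gompertz and constant families
  sits on a boundary of the parameter space; the battery compares them by
  AIC instead, and the nested LRT is reserved for term comparisons within
  a family.
* Thin-plate-spline visualization of calling surfaces is out of scope;
  `plot()` methods provide basic survival diagnostics only.
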