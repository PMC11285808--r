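---
title: "Models and methods behind flyvir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flyvir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

flyvir analyses a natural virus-exposure experiment in *Drosophila
melanogaster*: laboratory females are co-housed for a few days with
wild-caught "donor" flies, the donors of each vial are assayed as a pool for
a panel of RNA viruses, and each recipient female is then followed singly
until death (up to a 72-day limit), recording her day of death, her adult
offspring production, and — at death — which of the viruses she had been
exposed to she actually tested positive for. The statistical questions are:
how prevalent is each virus in the wild donors, how readily does it
transmit, and what does infection cost the host in lifespan and offspring
production?

This vignette documents the models, the estimators, the sampler, the
synthetic-data generator, and every numerically consequential choice.

## Pooled prevalence and support intervals

Donor flies are assayed in pools of 8–20, so individual wild prevalence $p$
is only observable through pool positivity: a pool of size $n$ is positive
with probability $1-(1-p)^n$. `estimate_prevalence()` maximises the
resulting Bernoulli likelihood over $p \in [0,1]$ by bounded golden-section
search (`stats::optimize`, tolerance $10^{-8}$; the likelihood is unimodal
in $p$). Intervals are *support intervals*: the set of $p$ within `drop`
natural-log-likelihood units of the maximum, located by bisection on each
side of the MLE. The default `drop = 2` follows the standard usage of the
pooled-testing literature (a drop of 2 in $\ln L$, with roughly 95.4%
asymptotic coverage by the $\chi^2_1$ likelihood-ratio argument); readers
who interpret "2 log-likelihood units" as a drop of 2 in $2\ln L$ can pass
`drop = 4`. All-negative and all-positive layouts return the boundary MLE
with a one-sided interval. With unit pools this machinery reduces exactly to
the binomial proportion, which is how `estimate_transmission()` computes
transmission rates (infected recipients / exposed recipients) with
intervals.

`fisher_exact_rxc()` is a full-enumeration Fisher–Freeman–Halton test for
r×2 tables (viruses transmitted / not transmitted per donor group): it sums
the multivariate hypergeometric probabilities of all tables with the
observed margins that are no more probable than the observed table, with a
$10^{-12}$ relative guard on the tie comparison. Enumeration is exact and
instantaneous at the table sizes that arise here.

## The MCMC engine

Both trait models run on a purpose-built sampler
(`gibbs_lmm()`, `hurdle_poisson_mcmc()`) rather than an external MCMC
package, so that every full conditional is documented and testable.

**Priors.** Fixed effects: independent $N(0, 10^{10})$. Variance
components: inverse-gamma in the $(V, \nu)$ parameterisation with
$V = 1, \nu = 0.002$ — the conventional weakly-informative default for this
model family. The original study does not state its priors, so these are
exposed in `prior_spec()` and the acceptance standard is parameter
*recovery*, not numerical replication of any published table.

**Gaussian mixed models.** `gibbs_lmm()` samples
$y = X\beta + \sum_j Z_j u_j + e$ by blocked Gibbs: $\beta$ and each
random-effect block from conjugate multivariate-normal full conditionals,
each variance from its conjugate inverse-gamma. Random-effect blocks may be
factors (vial) or indicator matrices whose rows load on several levels (the
per-virus deviations of a multiply infected fly in the infection-count
model). Rank-deficient fixed designs abort with the collinear columns
named; any non-finite draw aborts with its iteration index.

**Hurdle-Poisson models.** Offspring counts get two latent linear
predictors per female: the logit of P(zero offspring) and the log rate of a
zero-truncated Poisson for positive counts. Each trait has its own
baseline, fixed effects, vial random effect and latent residual variance;
the between-trait covariance is fixed at zero. Latent values are updated by
random-walk Metropolis with a single scale per trait, adapted toward 44%
acceptance during burn-in by a diminishing Robbins–Monro step and frozen
afterwards to preserve detailed balance. For zero counts the count-part
latent has no likelihood term and is drawn directly from its Gaussian
conditional. Everything else is conjugate.

**Chain geometry.** `run_config()` defaults to 20,000 iterations, 10%
burn-in, 2,000 recorded draws; thinning is
`floor((total - burn_in)/recorded)`. A full-scale analysis in the spirit of
the original would use $10^6$ iterations with $10^4$ recorded; the package's
tests use deliberately shorter chains (typically 1,200–2,000 iterations,
300–700 recorded) chosen so that parameter-recovery coverage is still
nominal — the coverage checks below verify exactly that.

**Summaries.** `hpd_interval()` returns the shortest contiguous window of
the sorted draws containing `ceiling(mass * n)` draws (ties broken toward
the smallest lower endpoint). `effective_sample_size()` uses the
initial-positive-sequence estimator $n / (1 + 2\sum_k \rho_k)$, truncated at
the first non-positive autocorrelation; a zero-variance chain is defined to
have ESS $= n$. `pmcmc()` is twice the smaller tail fraction relative to
zero, floored at $2/n$ and capped at 1. Summaries flag any parameter whose
ESS falls below a configurable floor (a full-scale run would demand several
thousand).

## Lifespan models

**Model A (per-virus effects).** Lifespan in days on an intercept (the
predicted uninfected baseline), one 0/1 indicator per virus for detection at
death, and a vial random intercept. Viruses with no infected flies are
inestimable and dropped, with a warning and a record in the fit.

**Model B (infection count).** Lifespan on the number of detected
infections as a continuous covariate, plus a per-virus random intercept that
applies only to infected flies — a female infected with $k$ viruses receives
the sum of her $k$ virus deviations, all sharing one variance — plus the
vial effect. This asks whether infections act additively and whether virus
identity matters beyond the shared slope.

**Censoring.** Females alive at the 72-day limit are, by default, analysed
as if they died at the limit, which is what a Gaussian lifespan model with
no censoring machinery implies; `censored = "exclude"` drops them instead.
With no censored flies the two options coincide exactly (and the test suite
checks that they do). A proper survival model is out of scope by design.

**Percent reductions.** `percent_reduction()` transforms each draw as
$100\,(-\beta_v / \mu_0)$, so the interval propagates uncertainty in both
the effect and the baseline. The baseline is the model intercept by
default; dividing by the observed uninfected mean is available via
`baseline = "uninfected_mean"` since either reading of "percent of
uninfected lifespan" is defensible.

## Fecundity models

`fit_fecundity()` fits lifetime offspring (`offspring_total`) or the
early-laying window (`offspring_early`, dropping females that died before
the window closed, so lifespan cannot leak into early fecundity). There is
no shared intercept across the two hurdle traits: each trait carries its own
baseline level, so the zero-part estimates read directly as sterility
logits rather than contrasts against the count part.

A virus enters the zero (sterility) part only when it is *estimable*: among
its infected females at least one produced zero offspring and at least one
produced some (`detect_zero_estimable()`; viruses whose infected females all
reproduced cannot inform a zero probability). All viruses with any infected
fly enter the count part. `percent_offspring_reduction()` transforms
count-part draws as $100\,(1 - e^{b_v})$.

`posterior_predictive_zeros()` simulates, for each recorded posterior draw,
a complete offspring vector at the observed covariates (that draw's fixed
effects and vial effects, fresh latent residuals, fresh hurdle and
truncated-Poisson draws) and compares the observed number of
zero-offspring females with the central 95% band of the simulated counts —
the standard check that a hurdle fit actually accounts for the zeros it was
built for.

`early_late_correlation()` reports the Pearson correlation between early
and late (total minus early) offspring with the Fisher-z interval, via
`stats::cor.test`.

## Power analysis

`simulate_power()` draws lifespans from the model-A generative process
(one virus at a $-\mathrm{pct}/100 \times \mu$ day effect, vials of 20
spanning both groups) and applies a detection rule. The default rule is the
Welch two-sample test — fast enough for curves and required-n searches; a
full Bayesian-fit rule (reject when the effect's pMCMC < $\alpha$) is
provided for spot-calibration, and the test suite checks the two rules
agree. `required_n()` bisects over the group size, either against the
simulation or against the closed-form two-sample normal power
(`analytic_power()`, with SD $\sqrt{\sigma_e^2 + \sigma_\text{vial}^2}$).
The lifespan mean and SDs must be supplied explicitly (e.g. 34 days and
$\sigma_e = 18$, the scale of this experiment); there are no hidden
defaults.

## The synthetic experiment generator

`generate_experiment()` mirrors the experiment's structure: vials per donor
species group, pool sizes uniform on 8–20, pool positivity iff at least one
carrier (per-fly carriage probabilities by group), 20 recipients per vial
exposed to their pool's positive viruses, independent per-virus Bernoulli
transmission, Gaussian lifespans with vial effects (observed as whole days,
floored at day 1, censored at day 72), hurdle-Poisson offspring with
per-trait vial effects and latent residuals, binomially thinned early-window
counts, and detection at death degraded by a sensitivity parameter
(default 1; misclassification only ever biases effects toward zero).

`paper_like_config()` freezes a configuration calibrated to the reported
outcomes: nine transmissible viruses; lifespan effects of −23, −17, −30,
−11 and −37% of a 38-day uninfected baseline for galbut virus, DmelNV,
DimmNV, Muthill virus and Prestney Burn virus; count-part offspring effects
of −46, −39 and −24% for DmelNV, DimmNV and Muthill virus, a +1 logit
sterility effect for Muthill virus, and a 10% baseline zero rate around a
102-offspring uninfected mean; $\sigma_\text{vial} = 3$ and
$\sigma_e = 18$ days (vial variance a small fraction of the total, residual
SD consistent with deaths spread over 1–72 days around a mean near 34).
Carriage and transmission probabilities were calibrated once, against the
closed-form expectations in `expected_infection_summary()`, to give about
606 exposed recipients of 860, about 35% of them infected, mostly singly.

What the generator does **not** emulate: dependence between viruses in
transmission (so it produces slightly fewer triple infections than were
observed), any coupling between a female's lifespan and her offspring count
beyond shared infection status, within-host dynamics or clearance (detection
error is a static sensitivity), and vial-level donor heterogeneity beyond
carriage probabilities. Passing tests therefore validate the *estimators*
under the assumed model family — they cannot certify the biological
assumptions themselves.

## What the test suite establishes

All expected values in the tests were computed from independent oracles
before being frozen: direct arithmetic for likelihoods and transforms,
grid searches for MLEs, window enumeration for HPD intervals, closed-form
conjugate posteriors and `lme4` maximum likelihood for the Gibbs sampler,
the closed-form zero-truncated-Poisson mean, `stats::fisher.test` for the
exact test, and `stats::power.t.test` for power. The headline calibration
checks, at the problem sizes the package uses for them:

- support-interval coverage ≈ 95.4% over 2,000 simulated pooled datasets;
- 95% HPD coverage of a −8 day effect across 200 replicate mixed-model fits
  at n = 600, and of a −0.6 log-rate effect across 200 hurdle fits;
- pMCMC rejection at 0.05 ≈ 5% across 400 true-null fits;
- simulated power matching the closed form across a 3×3 grid, and an
  analytic required n for a 1% lifespan reduction in the tens of thousands
  per group;
- an end-to-end run on the study-like configuration recovering the correct
  sign for every effect of at least 20%.

## Known limitations

Censoring is handled by analysing survivors at the limit, not by a survival
likelihood. The hurdle sampler's single-scale random-walk updates mix
slowly for the zero part when zeros are scarce — the ESS flags exist
precisely to surface this, and longer chains resolve it. Support intervals
rely on $\chi^2_1$ asymptotics and can under-cover for very few, very large
pools. The exact test enumerates all tables and is intended for the small
r×2 tables of this design, not for large counts.
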