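---
title: "Decision-theoretic trial design for small populations: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-theoretic trial design for small populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voitrial)
```

# The decision problem

`voitrial` designs a confirmatory two-arm RCT as an investment decision
made on behalf of society. The quantity being purchased is information: a
trial of total size $n$ (randomised 1:1) yields an observed mean difference
$\bar x \sim N(\theta, \tau^2/n)$, and the treatment is approved iff
$\bar x \ge z_\alpha \tau/\sqrt n$ — operationally identical to a one-sided
level-$\alpha$ significance test. What the conventional framing leaves
implicit, this one prices explicitly:

* the benefit $\theta$ of the experimental treatment, on a monetary scale,
  with prior $\theta \sim N(\mu_0, \sigma_0^2)$;
* the known addressable population $N$, of which a trial of size $n$
  consumes $n/\rho$ patients ($\rho$ is the proportion of concurrent
  patients enrolled), leaving $N - n/\rho$ to be treated per the decision;
* per-patient trial cost $c_1$, per-patient treatment cost or monetised
  harm $c_2$, and fixed cost $c_f$ (incurred only if $n > 0$).

Utilities are taken relative to treating everyone with the standard
treatment. On approval the $n/2$ experimental-arm patients plus all
$N - n/\rho$ future patients receive the treatment, each worth
$\theta - c_2$; on non-approval only the $n/2$ trial patients do. Averaging
over both the prior and the sampling distribution gives the closed form
evaluated by `expected_utility()`:

$$\mathcal G(n, z_\alpha) = (N - n/\rho)\left\{(\mu_0 - c_2)\Phi(-Z)
  + \frac{\sigma_0^2}{\sigma_x}\,\phi(Z)\right\}
  + \frac n2(\mu_0 - c_2) - c_1 n - c_f,$$

with $\sigma_x^2 = \sigma_0^2 + \tau^2/n$ the prior-predictive variance of
$\bar x$ and $Z = (z_\alpha\tau/\sqrt n - \mu_0)/\sigma_x$. The first brace
is the expected value of the approval option: the probability-weighted mean
benefit of treating the future population, plus an information premium
$(\sigma_0^2/\sigma_x)\phi(Z)$ that rewards deciding *after* seeing data.
Differentiating in $z_\alpha$ and solving gives the analytic optimal
threshold for any $n$ (`optimal_z()`):

$$z_\alpha^*(n) = c_2\frac{\sigma_x^2\sqrt n}{\sigma_0^2\tau}
  - \mu_0\frac{\tau}{\sigma_0^2\sqrt n}.$$

Only the one-dimensional maximisation over $n$ remains, done numerically.

## Assumptions worth stating

* Known sampling variance ($\tau^2$ fixed, no $t$-correction) and 1:1
  allocation; $n$ is even by construction.
* The $n(1-\rho)/\rho$ concurrent patients *not* enrolled receive the
  standard treatment and contribute zero relative utility — the utility
  function is followed literally, as no alternative accounting is defined.
* The decision-maker is risk-neutral in money; $\theta < 0$ (harm) is a
  loss, never truncated.
* $N$ is known and fixed; growth/decay of the population over the
  exclusivity horizon, uptake depending on observed efficacy, sequential
  or conditional approval are out of scope.

# Parameters, units, defaults

| Parameter | Meaning | Unit | Case-study value |
|---|---|---|---|
| `mu0` | prior mean effect | $ | 96,000 |
| `sigma0_sq` | prior variance | $² | 49,638² |
| `tau_sq` | sampling scale, `var(xbar) = tau_sq/n` | $² | 363,202² |
| `N` | addressable population | patients | 4,000 |
| `rho` | concurrent enrollment proportion | — | 0.2 |
| `c1` | per-patient trial cost | $/patient | 5,000 |
| `c2` | per-patient treatment cost/harm | $/patient | 61,032 |
| `cf` | fixed trial cost | $ | 1,000,000 |

All computation is in dollars; the `$ millions` renderings in printed
reports are presentation only. The default alternative for type II error
reporting is $\theta_A = \sigma_0/2$, the choice used throughout the
operating-characteristic surfaces; it is overridable everywhere it occurs.

# Numerical choices

**Search strategy.** `optimize_design()` evaluates the profile
$g(n) = \mathcal G(n, z_\alpha^*(n))$ on an even grid (step 2 by default,
i.e. exhaustively) over $[2, \lfloor\rho N\rfloor]$, then refines the best
bracket over *continuous* $n$ by golden-section search
(`stats::optimize`), and finally projects to the better of the two
adjacent even integers. The profile is smooth and, empirically, unimodal
over the feasible range in every scenario examined; the exhaustive coarse
grid makes the bracketing robust even if it were not.

**Two reporting conventions.** The published case-study threshold
($z^* = 0.36876$, $\alpha^* = 0.35615$) is consistent with the continuous
optimum near $n \approx 45.5$, not with $z_\alpha^*(46) = 0.3797$. Both
conventions are therefore exposed: by default `z_star` is reported at the
continuous maximiser (`z_convention = "continuous"`), with
`z_convention = "even"` re-evaluating it at the projected even $n^*$. The
reported utility `g_star` is always that of the even design at its own
optimal threshold, so it dominates every candidate on the even grid.

**No-trial boundary and sign conventions.** The $n = 0$ option is an
explicit branch, not a limit: its value is $\max(N(\mu_0 - c_2), 0)$,
avoiding the undefined $\sigma_x$ at $n = 0$. For reporting, approval
without a trial is encoded $z^* = -\infty$ ($\alpha^* = 1$), non-approval
$z^* = +\infty$ ($\alpha^* = 0$); at exact indifference ($\mu_0 = c_2$)
both actions are worth zero and the threshold is reported `NA`
("indifferent") rather than an arbitrary sign. In
`expected_utility(model, 0, z)` a finite `z` is interpreted by the sign of
the induced threshold $z\tau/\sqrt n \to \pm\infty$: negative `z` means
always-approve, non-negative means never-approve.

**Tie-breaking.** Candidates whose utilities agree within `refine_tol`
(relative, default $10^{-9}$) are resolved toward the smaller $n$, and
toward $n = 0$ against the no-trial branch: under indifference, fewer
patients are exposed at no loss.

**Boundary searches.** `find_population_threshold()` brackets by doubling
and then bisects over *integer* $N$, so the returned
`N_first_trial`/`N_last_no_trial` pair is exact for the model and
deterministic; any rounding to a printed precision happens at the
reporting layer, never inside the search.

# The Monte Carlo oracle

`simulate_expected_utility()` exists to validate the closed form, not to
replace it: it draws $\theta$ from the prior, $\bar x$ from the sampling
model, applies the decision rule and scores the realised utility — the
preposterior double integral done by brute force. A single `set.seed(seed)`
with vectorised draws makes runs exactly reproducible. The test suite also
integrates the pointwise utility against the posterior and prior-predictive
densities by adaptive quadrature, an oracle that exercises the conjugate
algebra independently of both the closed form and the simulation.

A green oracle test establishes that the closed form, the simulation and
the quadrature agree *with each other* under the stated normal-normal
world. It does not establish that a real binary endpoint is adequately
normal at small $n$, that $\tau^2$ is truly known, or that the monetary
valuation is right — those are modelling judgements outside the package.

# The case-study fixture and the binary-endpoint mapping

`build_model()` maps arm-level binary summaries to the monetary model:
$\mu_0 = \lambda(\hat\mu_E - \hat\mu_S)$,
$\sigma_0^2 = \lambda^2(\hat\sigma^2_{0E} + \hat\sigma^2_{0S})$ with
$\hat\sigma^2_{0t} = \hat\mu_t(1-\hat\mu_t)/n_{0t}$, and the
unequal-variance sampling scale
$\tau^2 = 2\lambda^2(\hat\sigma^2_E + \hat\sigma^2_S)$ — a large-sample
normal approximation with no continuity correction.

The fixture `haemophilia_model()` pins the *published rounded* monetary
values ($\sigma_0 = \$49{,}638$, $\tau = \$363{,}202$, …) rather than
recomputing them from the arm summaries, because every published result
($n^* = 46$, \$141M, the boundary populations) is anchored to those rounded
figures; `build_model()` on the arm table agrees with the fixture to well
within 0.1% and is tolerance-tested, not bit-tested, against it.

# Known limitations and two discrepant published boundaries

Implementing the stated equations exactly, two of the four published
no-trial boundary figures do not reproduce at their printed precision,
while their neighbours do:

* at the case-study cost ($c_2 = \$61{,}032$) the computed boundary is
  $N = 3{,}415$ (published: below 3,000 no trial — agrees at the printed
  nearest-1,000 rounding);
* at $c_2 = \mu_0$ the computed boundary is $N = 184$ (published 200;
  agrees at nearest-100);
* at $c_2 = 0$ the computed smallest trial-running population is
  $N = 372{,}621$ (published 390,000 at nearest-10,000);
* at $c_2 = \$120{,}819$ the computed largest no-trial population is
  $N = 599$ (published 640 at nearest-10).

The computed values are confirmed by an exhaustive even-$n$ grid scan
independent of the package optimiser, and the surrounding operating
characteristics (monotone $n^*$ and $\alpha^*$, the $\sqrt N$ growth law,
the $\beta^*$ limits) all reproduce. The two outliers are plausibly
read off a coarse population grid in the original operating-characteristic
sweeps; this package reports what the model computes and leaves the
corresponding acceptance expectations red rather than tuning toward the
printed numbers.

Beyond that: the method presumes a meaningful monetary valuation $\lambda$
and an elicitable prior — with very informative priors the optimum is often
"no trial", which regulators may find unacceptable; frequentist error rates
are outputs, not constraints, and can be far from conventional levels; and
the utility is linear in $\theta$, so risk aversion, equity weights and
discounting over the horizon are all outside the model.
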