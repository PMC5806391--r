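# voitrial

Value-of-information (VOI) design of confirmatory randomised controlled
trials in small populations.

When a disease is rare, recruiting enough patients for conventional error
rates (one-sided α = 0.025, power 80–90%) may be infeasible — and, more
fundamentally, conventions that ignore how many patients will ever receive
the treatment can be the wrong target. `voitrial` takes a Bayesian
decision-theoretic view: the trial is an investment made on behalf of
society, and both the sample size *and* the significance threshold are
chosen to maximise the expected monetary utility of the whole programme —
patients treated in the trial, patients treated afterwards if the treatment
is approved, and the financial cost of finding out.

## The model

A two-arm 1:1 trial of total size *n* observes a mean difference
x̄ ~ N(θ, τ²/n), where θ is the per-patient monetary benefit of the
experimental over the standard treatment, with prior θ ~ N(μ₀, σ₀²). The
regulator approves the treatment iff x̄ ≥ z_α·τ/√n — a one-sided level-α
test. With a known population of size *N*, trial enrollment proportion ρ
(so a trial of size *n* consumes n/ρ patients), per-patient trial cost c₁,
per-patient treatment cost or harm c₂, and fixed cost c_f, the
preposterior expected utility has the closed form

    𝒢(n, z_α) = (N − n/ρ) { (μ₀ − c₂) Φ(−Z) + (σ₀²/σ_x) φ(Z) }
                + (n/2)(μ₀ − c₂) − c₁ n − c_f ,

where σ_x² = σ₀² + τ²/n is the prior-predictive variance of x̄ and
Z = (z_α·τ/√n − μ₀)/σ_x. For each *n* the optimal threshold is analytic,

    z_α*(n) = c₂ σ_x² √n / (σ₀² τ) − μ₀ τ / (σ₀² √n),

and the package maximises 𝒢(n, z_α*(n)) over *n* numerically, comparing
against the no-trial alternative (approve on the prior alone when μ₀ > c₂,
worth N(μ₀ − c₂); otherwise keep the standard treatment, worth 0). Small
populations therefore get small — sometimes zero — optimal trials, with
significance levels far from 0.025, while the optimal threshold tightens as
the population grows whenever treating future patients carries a cost.

## Worked example: haemophilia A

The bundled case study compares tailored prophylaxis (TP, experimental)
with on-demand treatment (OD, standard) of recombinant factor VIII for
severe haemophilia A. The endpoint is absence of MRI-detected joint damage,
valued at λ = $400,000 per unit efficacy; the addressable population is
N = 4,000 (200 incident cases/year over a 20-year market-exclusivity
horizon) with ρ = 0.2 of concurrent patients enrollable.

```r
library(voitrial)

model <- haemophilia_model()
fit <- optimize_design(model)
fit
#> <voi_design>  value-of-information optimal trial design
#>   n* = 46 patients (23 per arm); z* = 0.36890 (alpha* = 0.35610, continuous-n convention)
#>   expected utility: $141.29 million (no-trial alternative: $139.87 million)
```

The optimal trial randomises only 23 patients per arm and approves at
z* ≈ 0.369 — a one-sided significance level of about 0.356, fourteen times
the conventional 0.025. The conventional design is much larger and worth
less:

```r
conventional_design(model, alpha = 0.025, beta = 0.8)
#> # A tibble: 1 × 6
#>       n z_alpha alpha  beta theta_a          g
#>   <int>   <dbl> <dbl> <dbl>   <dbl>      <dbl>
#> 1   268    1.96 0.025   0.8   24819 109985209.
```

i.e. n = 268 for 20% power at the alternative θ_A = σ₀/2 = $24,819, with
expected utility $110.0M versus $141.3M at the optimum. The closed form can
be checked against forward simulation from the prior and sampling model:

```r
run_validate(model, replicates = 1e5, seed = 1)
#> Monte Carlo validation of the closed-form expected utility
#>   design        : n = 46, z_alpha = 0.36890
#>   closed form   : $141.2896 million
#>   simulation    : $141.1617 million (SE $0.5372 million, 100000 replicates, seed 1)
#>   discrepancy   : -0.24 SE -> PASS (within 3 SE)
```

and the no-trial boundary located exactly:

```r
find_population_threshold(model)
#> # A tibble: 1 × 4
#>      c2 N_first_trial N_last_no_trial status
#>   <dbl>         <dbl>           <dbl> <chr>
#> 1 61032          3415            3414 threshold
```

Below N = 3,415 the optimal action is to approve tailored prophylaxis on
the prior alone. `sweep_designs()` tabulates n*, z*, α*, β* and 𝒢* over
grids of N and c₂ (with `autoplot()` methods for both the sweep and the
utility profile), and `read_scenario()` / the `inst/cli/voitrial.R` script
expose the same operations for flat `key: value` scenario files.

## Acceptance script

`scripts/acceptance.R` recomputes the case-study quantities from scratch
with the installed package — the optimal design (n*, z*), the conventional
comparator's expected utility, and the four no-trial population boundaries
at treatment costs $61,032, $0, $96,000 and $120,819 — and writes them as
JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
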