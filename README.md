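# pulsechase

Pulse-length-aware analysis of macromolecule decay from pulse-chase
experiments.

## What problem this solves

Pulse-chase experiments label molecules (proteins, mRNA) synthesized during
a pulse of duration *t*<sub>p</sub>, then track the labeled cohort's
relative abundance during the chase. For non-exponential degradation the
labeled population at chase start is a *mixture of molecule ages* whose
composition depends on the pulse length — so the decay pattern, and any
half-time read off it, changes with *t*<sub>p</sub>. Fitting decay curves
without modeling the pulse therefore returns biased kinetics.

`pulsechase` is for experimentalists and modelers who want degradation
parameters that are comparable across protocols. It models the lifetime as
the absorption time of a two-stage Markov chain — state 1 (rates
κ<sub>10</sub> to degradation, κ<sub>12</sub> to state 2) and state 2 (rate
κ<sub>20</sub>) — a phase-type distribution with survival
*S*(*t*) = *w*<sub>1</sub>e<sup>−λ₁t</sup> + *w*<sub>2</sub>e<sup>−λ₂t</sup>,
λ₁ = κ<sub>10</sub>+κ<sub>12</sub>, λ₂ = κ<sub>20</sub>. The chase curve for
any pulse length is the closed form

    C(Δt) = [A_c e^(−λ₁Δt) + B_c e^(−λ₂Δt)] / (A_c + B_c)
    A_c = (κ10 − κ20)/λ₁ · [1 − e^(−λ₁ t_p)]
    B_c = κ12/κ20 · [1 − e^(−λ₂ t_p)]

(with *t*<sub>p</sub> → ∞ the synthesis-shutoff limit, *t*<sub>p</sub> → 0
the survival function, and κ<sub>12</sub> = 0 the pulse-independent
exponential). A matching closed form covers the pulse-only (no chase)
design. The package provides:

- closed-form curves, hazard rate, age distributions, mean lifetime,
  occupancies, half-times (`chase_curve`, `pulse_only_curve`,
  `hazard_rate`, `derived_quantities`, ...);
- bounded multistart least-squares fitting on log abundances, pooling any
  number of patterns with different pulse lengths and designs
  (`fit_decay`), plus AIC model selection against the exponential model
  (`compare_decay_models`);
- a synthetic-data module: noiseless fabricated patterns, the one-sided
  multiplicative noise model, and an independent single-molecule stochastic
  simulator (`fabricate_pattern`, `add_noise`,
  `simulate_single_molecules`);
- closed-form local sensitivities of the pulse-only output with a
  finite-difference oracle (`pulse_sensitivity`);
- delimited pattern tables, JSON reports, and a CLI
  (`inst/cli/pulsechase.R` with `simulate` / `fit` / `derive` /
  `sensitivity` subcommands).

## Worked example

Fabricate decay patterns at three pulse lengths from reference
protein-turnover rates, perturb them with 1% multiplicative noise, and
re-estimate the rates jointly:

```r
library(pulsechase)

r <- rate_set(0.0109, 0.0189, 0.0002)            # min^-1
pats <- lapply(c(1, 30, 1200), function(tp)
  fabricate_pattern(r, tp, times = seq(0, 480, 40)))
noisy <- lapply(seq_along(pats), function(i)
  add_noise(pats[[i]], epsilon = 0.01, seed = i))

fit <- fit_decay(noisy, starts = 200, seed = 1)
fit
#> Decay fit (two_stage model): 3 pattern(s), 39 points, 200 starts
#>   kappa10 = 0.0108642  kappa12 = 0.0190324  kappa20 = 0.000191992  (min^-1)
#>   objective M = 0.000381443 (log-RSS), AIC = -443.869
#>   6 near-equivalent minimum(-ima) within tie tolerance

derived_quantities(fit$rates)
#> Derived kinetic quantities (two-stage model)
#>   mean lifetime       : 3349 min (55.8 h)
#>   half-time (t_p = Inf): 3592 min
#>   occupancies         : pi1 = 0.009987, pi2 = 0.99
#>   dwell times         : tau1 = 33.45 min, tau2 = 5209 min
#>   branching           : P10 = 0.3634, P12 = 0.6366
#>   steady state        : N_st = 3349 (omega = 1 min^-1)
```

The pooled fit recovers the generating rates to within a few percent
despite the noise; the mean lifetime (~56 h here, 53.4 h at the true rates)
is the stability measure to report, since the apparent half-time varies
with the pulse length (compare `half_time(r, 1)` ≈ 1249 min with
`half_time(r, 1200)` ≈ 3377 min and `half_time(r)` ≈ 3447 min at infinite
pulse). Most molecules (π₂ ≈ 0.99) sit in the slow second state at steady
state, which is why long pulses hide the fast first stage — prefer short
pulses, or pool several pulse lengths as above.

The same pipeline runs from the shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "pulsechase.R", package = "pulsechase"))')
Rscript "$CLI" simulate --k10 0.0109 --k12 0.0189 --k20 0.0002 \
    --pulse 1,30,1200 --epsilon 0.01 --out-prefix demo
Rscript "$CLI" fit demo_p1.csv demo_p30.csv demo_p1200.csv --out fit.json
Rscript "$CLI" derive --k10 0.0109 --k12 0.0189 --k20 0.0002
```

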