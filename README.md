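# timealloc

Microscopic and macroscopic models of how subjects divide limited time
between work and leisure.

On a cumulative handling time schedule a subject must accumulate `P` seconds
of work (the *price*) to earn one reward of subjective intensity `R_I`; in
between, it is free to take leisure bouts of any length.  The striking
empirical fact is *partial allocation*: except at extreme payoffs, subjects
spend part of their time working and part at leisure.  `timealloc` is for
computational neuroscientists and behavioral economists who want the
microscopic, normative account of this fact as executable, testable code —
together with the classical macroscopic accounts it subsumes, and the
machinery connecting the two levels.

## The model

The microscopic model is a two-state, average-reward semi-Markov decision
process.  Each cycle is a chosen leisure bout of duration τ followed by a
price-long work bout.  Leisure has an innate utility `U_L(τ)` (linear
`C_L·τ`, or concave `C_L·log(1+τ)` / `C_L·log τ`); a policy π over durations
earns the average reward rate

    ρ = (R_I + E_π[U_L(τ)]) / (P + E_π[τ]),

and committing to a bout forgoes `ρ·τ` — the average foregone reward, the
opportunity cost of time.  Subjects value policy entropy `H(π)` with weight
`1/β`, so the optimal policy is the softmax over differential Q-values

    Q(τ) = U_L(τ) − ρ τ + V_pre,
    π(τ) ∝ exp(β Q(τ))   on [0, τ_max],

solved jointly with ρ as a fixed point.  Closed forms: a truncated
exponential with rate `β(ρ − C_L)` for linear utility, a truncated gamma
with shape `β C_L + 1` and rate `β ρ` for log utility.

Averaging cycles gives the macroscopic time allocation
`TA = P/(P + E[τ])`.  The package also implements the two traditional
macroscopic accounts — CES labor-supply utility
`U(K, L) = (w_K K)^σ + (w_L L)^σ` maximized on the trial-time budget
`K·P + L = T`, and the generalized-matching "mountain"
`TA/(1−TA) = ((R_I/P)/(R_max/P_e))^a` — and *derives* a macroscopic utility
from the microscopic model whose budget-constrained optimum reproduces the
SMDP allocation, with the Lagrange multiplier on the micro-macro
consistency constraint equal to the reward rate (`λ = ρ`, the shadow-price
identity).  Headline predictions: partial allocation needs neither
stochasticity nor imperfect substitutability (concave `U_L` with
deterministic choice suffices), and for concave `U_L` the time allocated to
work can *increase* with price at long prices, which no monotone mountain
model can produce.

## Worked example

```r
library(timealloc)

task <- task_spec(R_I = 10, P = 5, tau_max = 10)   # payoff 2 utility/s
u    <- leisure_utility("linear", C_L = 0.5)
pol  <- solve_policy(task, u, policy_settings(beta = 1))
pol
#> <solved_policy> beta = 1, R_I = 10, P = 5 s
#>   rho = 1.80001 /s, mean leisure = 0.769198 s, TA = 0.8667
```

The solved reward rate is 1.80 utility/s, so every second of leisure
forgoes 1.8 utility while paying only `C_L = 0.5`: leisure bouts are short
(mean 0.77 s against a price of 5 s) and the subject works 86.7% of the
time.  The policy is exactly the truncated exponential with rate
`β(ρ − C_L) = 1.30 /s`:

```r
closed_form_distribution(u, beta = 1, rho = pol$rho, tau_max = 10)$rate
#> [1] 1.300007
```

Deterministic choice with concave leisure utility still yields partial
allocation, and the derived macroscopic utility agrees with the micro
model exactly, with the shadow price equal to the reward rate:

```r
consistency_check(leisure_utility("log1p", 5), beta = Inf,
                  task_spec(10, 5, tau_max = 20), grid_n = 1001)
#>   TA_macro TA_micro delta_TA lambda   rho delta_lambda_rho
#>     0.8034   0.8034 1.11e-16  2.249 2.249                0
```

Simulated ethograms realize the same policy bout by bout
(`simulate_trial(task, pol, seed = 1)` gives an empirical TA of 0.836 for
one 125 s trial), and `ta_sweep()` / `mountain_surface()` map TA over the
reward-intensity × price plane; `autoplot()` methods draw densities,
surfaces, ethograms and indifference curves.  A thin command-line wrapper
(`inst/cli/timealloc`) exposes `solve`, `sweep`, `simulate`, `macro`,
`matching` and `ces` subcommands driven by YAML/JSON configs.

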