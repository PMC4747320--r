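# sexratioAD

Adaptive dynamics of primary sex ratio evolution in two-sex,
stage-structured matrix population models.

## What this is for

Why are birth sex ratios near 1:1 in so many species, and what bends them?
Verbal arguments (Fisher's equal-investment principle and its successors)
answer with two-generation bookkeeping and no life-cycle structure. This
package answers demographically: it builds a continuous-time, five-stage,
two-sex matrix model — juvenile and single adult males and females plus
reproducing unions (pairs), coupled through a harmonic-mean mating function
— and analyses the evolution of the primary sex ratio `s1` (proportion of
offspring born male) with adaptive dynamics.

For a resident strategy the nonlinear frequency dynamics
`dp/dt = (I − p1ᵀ) A(p) p` are integrated to the equilibrium stage
distribution `p̂`; a rare mutant playing `s1′` in that environment has
invasion fitness `s_x(y) = λ′(p̂) − λ`, the difference of dominant
eigenvalues of the mutant and resident projection matrices
`A = (T + B + U)/3`. The analytic selection gradient
`(w′ᵀ ⊗ v′ᵀ) dvecA′/ds1′` locates evolutionarily singular strategies, and
analytic second derivatives of invasion fitness (vec/Kronecker matrix
calculus, eigenvector Jacobians by resolvent solves) classify their
evolutionary stability (ESS / selectively neutral weak-form ESS /
branching point) and convergence stability (attractor / repeller).

Five offspring-cost interpretations are built in (identical sexes;
per-birth resource costs; offspring mortality during parental investment;
offspring mortality after investment; parental mortality costs), plus a
four-stage no-union contrast model, pairwise invasion plots, cost-parameter
sweeps, and the reproductive-value identities that hold at singular
strategies (`v_m1/v_f1 = Cm/Cf` for resource costs; `v_m1 = v_f1` under
after-investment mortality).

Audience: evolutionary demographers and theoretical ecologists working on
two-sex models, sex allocation, or adaptive dynamics of stage-structured
populations.

## Worked example

```r
library(sexratioAD)

# Case 1 (sex-specific resource costs), symmetric point, productive unions
mod <- build_case_model(life_cycle_params("productive"),
                        cost_model(1, Cm = 0.5, Cf = 0.5))
find_singular_strategy(mod)
#> Singular strategy report — 5-stage, Case 1, productive preset
#>   s1* = 0.50000000  (|gradient| = 1.16e-11)
#>   evolutionary stability value  = +0.000000  [weak-form-ESS (selectively neutral)]
#>   convergence stability value   = -0.917416  [attractor]
#>   s2* = 0.500000,  v_m1/v_f1 = 1.000000,  lambda = 0.522439
```

The equal sex ratio is a singular strategy; the evolutionary-stability
value is numerically zero (any rare mutant is exactly as fit as the
resident — selective neutrality) while the convergence value −0.917 < 0
makes it an evolutionary attractor: populations evolve toward 0.5 and then
stay, a convergence-stable weak-form ESS.

Biased costs shift the singular point toward the cheaper sex, further so
for resource-poor unions:

```r
mod <- build_case_model(life_cycle_params("poor"),
                        cost_model(1, Cm = 0.65, Cf = 0.35))
ss <- find_singular_strategy(mod)
c(s1_star = ss$s1_star, baseline = equal_investment_ss(0.65, 0.35),
  rv_ratio = ss$rv_ratio)
#>   s1_star  baseline  rv_ratio
#> 0.3066705 0.3500000 1.8571429
```

Sons cost 65% of the budget per birth, so the Fisherian baseline is
`Cf/(Cm+Cf) = 0.35`; the demographic model pushes further (0.307) because
poor unions blunt the mating advantage of the rarer sex — while the
reproductive-value ratio still obeys `v_m1/v_f1 = Cm/Cf = 1.857` exactly.

Other entry points: `solve_equilibrium()`, `selection_gradient()`,
`classify()`, `pairwise_invasion_plot()`, `sweep_case()`,
`four_stage_model()`, `rv_ratio_at_ss()`; a small CLI lives in
`inst/cli/sexratio-tools` (subcommands `equilibrium`, `find-ss`,
`classify`, `pip`, `sweep`, `fixtures`).

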