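---
title: "Adaptive dynamics of the primary sex ratio in two-sex matrix models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive dynamics of the primary sex ratio in two-sex matrix models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexratioAD)
```

## The model

The primary sex ratio $s_1$ — the proportion of offspring born male — evolves
under frequency-dependent selection: whichever sex is overproduced has fewer
mating opportunities. Classical treatments (Fisher's equal-investment
argument and its descendants) compress the whole life cycle into a
two-generation bookkeeping of grandchildren. This package instead embeds the
question in an explicitly demographic, two-sex, continuous-time matrix
population model and analyses it with adaptive dynamics.

The core life cycle has five stages in the fixed order
$(m_1, m_2, f_1, f_2, u)$: juvenile and single adult males, juvenile and
single adult females, and reproducing unions (monogamous pairs, the only
stage that produces offspring). Three rate matrices act on the stage
densities:

* **Union formation** $\mathbf{U}(p)$, built from the harmonic-mean mating
  function $M = 2 m_2 f_2 / (m_2 + f_2)$ with per-capita rates
  $U_m = M/m_2$, $U_f = M/f_2$. Harmonic-mean mating is homogeneous of
  degree one in abundances, so per-capita rates depend only on stage
  *frequencies* — the source of the model's frequency dependence.
* **Births** $\mathbf{B}(s_1)$: unions invest resources at a fixed total
  rate $R$; with an average cost $C_a(s_1) = s_1 C_m + (1-s_1) C_f$ per
  birth, sons arrive at rate $R s_1 / C_a$ and daughters at
  $R (1-s_1)/C_a$.
* **Transitions** $\mathbf{T}$: maturation ($\alpha_m, \alpha_f$), mortality
  ($\mu_{m1}, \mu_{m2}, \mu_{f1}, \mu_{f2}$), and union dissolution by
  divorce ($d$) or partner death, which returns the widowed survivor to the
  singles pool.

The projection matrix is the average $\mathbf{A}(p) = \tfrac13(\mathbf{T} +
\mathbf{B} + \mathbf{U}(p))$. The $1/3$ factor is kept verbatim: it rescales
time and the growth rate but moves no equilibrium and flips no stability
sign; reported derivative magnitudes (e.g. the $-0.92$ convergence value
below) are on this scale. Because $\mathbf{A}$ depends on frequencies only,
the stage distribution obeys the replicator-like equation
$\dot p = (I - p\mathbf{1}^\top)\mathbf{A}(p)\,p$, which converges to an
equilibrium $\hat p$; the population then grows exponentially at the
dominant eigenvalue $\lambda$ of $\mathbf{A}(\hat p)$, whose right
eigenvector is $\hat p$ itself and whose left eigenvector $v$ holds
stage-specific reproductive values.

## Invasion fitness and stability conditions

A rare mutant playing $s_1'$ in a resident population at $\hat p(s_1)$ has
projection matrix $\mathbf{A}'$ in which the mating rates are frozen at the
resident equilibrium (mutants are too rare to change the mating market, and
mate only with residents) while the birth allocation uses $s_1'$. Invasion
fitness is $s_x(y) = \lambda'(\hat p) - \lambda$, and the selection gradient
is the eigenvalue perturbation
$\partial \lambda'/\partial s_1' = (w'^\top \otimes v'^\top)\,
d\,\mathrm{vec}\mathbf{A}'/d s_1'$.

Singular strategies $s_1^*$ are roots of the gradient. They are classified
by two second derivatives of invasion fitness:

* the **pure mutant curvature** $\partial^2\lambda'/\partial s_1'^2$
  (negative: ESS; zero: selectively neutral "weak-form" ESS; positive:
  branching point), assembled from the analytic Hessian of $\lambda'$ with
  respect to the matrix entries (built from the Jacobians of $w'$ and $v'$,
  obtained by resolvent solves) plus the curvature of $\mathbf{A}'$ in
  $s_1'$;
* the **convergence value** $\partial^2\lambda'/\partial s_1'^2 +
  \partial^2\lambda'/\partial s_1 \partial s_1'$ (negative: evolutionary
  attractor; positive: repeller), where the mixed derivative differentiates
  the gradient through the resident equilibrium $\hat p(s_1)$.

At any singular strategy the three second derivatives satisfy the identity
$\partial^2\lambda'/\partial s_1'^2 + 2\,\partial^2\lambda'/\partial s_1
\partial s_1' + \partial^2(\lambda'-\lambda)/\partial s_1^2 = 0$, which the
test suite closes against an all-finite-difference resident curvature to
below $10^{-6}$ — a stringent end-to-end check of the equilibrium solver,
the eigenvector Jacobians, and the mixed derivative at once.

## Offspring-cost cases

Five interpretations of sex-biased offspring costs are wired into
`build_case_model()`:

| Case | Asymmetry | Key finding reproduced |
|------|-----------|------------------------|
| 0 | none | $s_1^* = 0.5$, selectively neutral, convergence stable |
| 1 | resource cost per birth ($C_m \ne C_f$) | cheaper sex favoured; *poor* unions overshoot the equal-investment value |
| 2 | mortality during investment | higher-mortality (cheaper) sex favoured at birth; secondary ratio less biased |
| 3 | mortality after investment | juvenile bias favours the surviving sex, adult bias the *dying* sex — after-investment mortality does bias $s_1^*$ |
| 4 | parental mortality per offspring | sex that spares its parents favoured |

Case 2 converts an investment rate $I$ and the juvenile mortality
$\mu$ into an expected cost per birth
$(I/\mu)(1 - e^{-\mu/\alpha})$ (age of independence $1/\alpha$); the
`expm1` form is used and the $\mu \to 0$ limit $I/\alpha$ is patched in
explicitly. Case 4 raises *mated* adult mortality by $c\,E$ with
$E = U R\,[s_1 D_m + (1-s_1)D_f]$; single adults are unaffected, so only
the union column of $\mathbf{T}$ changes.

At every singular strategy the reproductive-value identities hold:
$v_{m1}/v_{f1} = C_m/C_f$ for Cases 1–2, $v_{m1} = v_{f1}$ for Case 3
(mortality after investment cannot bias the *reproductive-value* ratio,
even though it biases $s_1^*$), and the Case 4 relation
$v_{m1} = v_{f1} + c (D_f - D_m)(U_f v_{m2} + U_m v_{f2} - (U_m+U_f)v_u)$,
collapsing to Case 3 as $c \to 0$.

A 4-stage contrast model without unions (`four_stage_model()`) lets adults
reproduce directly at per-capita fertilities $F_m = RM/(2m_2)$,
$F_f = RM/(2f_2)$ (the $1/2$ avoids double-counting each birth through both
parents). There the mating advantage of the rarer sex is automatically
proportional to its offspring-production advantage, and $s_1^* = 0.5$ is
restored exactly under any sex-biased mortality — isolating union formation
as the mechanism behind the 5-stage biases.

## A worked classification

```{r case1}
mod <- build_case_model(life_cycle_params("productive"),
                        cost_model(1, Cm = 0.5, Cf = 0.5))
find_singular_strategy(mod)
```

The evolutionary-stability value is numerically zero and the convergence
value is $\approx -0.92$: the equal sex ratio is a selectively neutral,
convergence-stable weak-form ESS. Every singular strategy across the Case
1–4 sweeps in the test suite carries the same pair of labels.

## Numerical choices

* **Equilibrium solver.** The frequency ODE is integrated with an embedded
  Dormand–Prince RK5(4) pair (no ODE suite is assumed available) in windows
  of 50 time units from a uniform start; once consecutive window ends agree
  to $10^{-4}$, a projected Newton iteration on
  $F(p) = \mathbf{A}(p)p - (\mathbf{1}^\top\mathbf{A}(p)p)\,p$ under the
  simplex constraint polishes the root to the requested residual (default
  $10^{-10}$, near machine precision when asked). Newton-converged points
  are accepted only if the frequency-dynamics Jacobian restricted to the
  simplex tangent space has no growing direction: Newton happily lands on
  single-sex saddle equilibria (where mating stops and the gradient is
  trivially zero), and at extreme $s_1$ under strong adult-mortality bias
  such boundary states can even be the genuine attractor. The
  singular-strategy scanner therefore also discards equilibria with no
  mating activity before bracketing roots.
* **Derivative steps.** First derivatives of eigenvalues use analytic
  formulas throughout; the only finite difference on the analytic path is
  the resident-equilibrium sensitivity $d\hat p/ds_1$ (central, step
  $10^{-5}$), with the two flanking equilibria solved to $10^{-13}$ —
  at the default $10^{-10}$ the $O(\mathrm{tol}/h)$ differencing error
  (~$10^{-5}$ relative) would swamp the $10^{-6}$ identity budget. All
  analytic derivatives are validated against independent central-difference
  oracles (steps $10^{-6}$ for gradients, $10^{-4}$ for curvatures) at
  relative error $10^{-4}$ or better.
* **Root finding.** The gradient is scanned on a 25-point grid over
  $[0.01, 0.99]$, sign changes are bisected with `uniroot` to
  $|s| < 10^{-12}$, and a neutrality band
  $|\mathrm{es}| < 10^{-4}(1 + |\mathrm{conv}|)$ maps the numerically-zero
  mutant curvature to the "weak-form ESS" label — the evolutionary-
  stability condition of this model class is exactly neutral in theory and
  never exactly zero in floating point.
* **Degenerate inputs.** Absent sexes give zero mating rates (the continuous
  limit of the harmonic mean); $C_a = 0$ raises an error; complex or tied
  dominant eigenvalues raise errors rather than proceeding.

## What the random fixtures do and do not establish

`generate_fixture()` draws parameter sets with mortalities and maturation
rates in $[0.01, 2]$, $R \in [1, 50]$, $d \in [0, 2]$ and positive costs —
wide enough to exercise growing and declining populations, fast and slow
life cycles, and all five cost cases. Property tests (fitness vanishing at
equal traits, FD agreement of all analytic derivatives, equilibrium
start-independence) run over these fixtures. They do not emulate real
census data: no stochasticity, no density dependence, no mating functions
other than the harmonic mean, and only monogamous pair unions. A green
suite establishes internal mathematical consistency of the model family and
exact reproduction of its closed-form special cases, not fit to any
empirical population.

## Known limitations

Only the scalar sex-ratio trait evolves (no vector traits); transient
evolutionary dynamics (canonical equation) and the full eight-type
singular-strategy taxonomy beyond the two binary conditions are out of
scope, as are mutual-invasibility/dimorphism analysis, nonlinear returns on
investment, and cooperative-breeding extensions. Configs are JSON (no YAML
reader is assumed). The Case 4 variant in which parents keep paying
mortality costs until offspring independence is not implemented; costs are
fixed at birth.
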