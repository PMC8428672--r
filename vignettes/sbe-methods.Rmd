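---
title: "Modelling snakebite envenoming interventions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling snakebite envenoming interventions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbecontrol)
```

## The model

Snakebite envenoming (SBE) is modelled as a coupled human–snake system.
The human population is split into unaware susceptibles $S_U$, aware
susceptibles $S_E$, envenomed individuals $I$, early and late antivenom
treatment classes $T_E, T_L$ (treatment within vs after 24 hours of the
bite), early-adverse-reaction classes $V_E, V_L$, and recoveries with and
without disability $R_D, R_W$.  The snake population $N_S$ grows
logistically towards a carrying capacity $K_S$ with natural mortality
$\mu_S$, and $D$ accumulates SBE deaths.  The per-susceptible envenoming
hazard is frequency dependent,

$$\lambda(t) = \beta \frac{N_S}{N_H + N_S},$$

so bites scale with the chance that an encounter involves a snake.
Awareness campaigns move susceptibles from $S_U$ to $S_E$ at rate
$\varepsilon$ and reduce the hazard of the aware by the efficacy factor
$(1 - \theta)$.  Envenomed individuals are treated at rate $\tau$, a
fraction $k$ of them early; early treatment carries no death or disability
risk, while the late classes die at rate $\delta_2$ and recover with
disability with probabilities $\rho_1, \rho_2$.  Recovered individuals
return to the aware susceptible class.

Two variants share one right-hand side.  In the *constant-control* system
the late death rate $\delta_2$ acts unconditionally on $T_L$ and $V_L$; in
the *time-dependent-control* system the controls $u_1(t)$ (awareness
effort) and $u_2(t)$ (treatment effort) multiply $\varepsilon$ and $\tau$,
and late deaths carry a $(1-u_2)$ factor, so full treatment effort removes
late mortality.  The two variants genuinely differ at $u_1 = u_2 = 1$ (by
exactly the $\delta_2$ terms), which is why the package keeps an explicit
`model = "constant" / "control"` switch rather than treating one as a
special case of the other.

Seven cumulative-flow trackers (new envenomings, early/late treatment
starts, adverse reactions during early/late treatment, recoveries with and
without disability) are integrated alongside the compartments.  Together
with $D$ they produce exactly the eight monthly cumulative series that
hospital snakebite registries report, which is what calibration fits.

## Units and the month time grid

All simulation is done with the **month** (365/12 days) as time unit, and
the packaged transmission, treatment and recovery rates are taken per
month.  This choice is deliberate: the parameter set was estimated against
monthly cumulative registry series indexed by month number, and only under
a month time unit do the packaged estimates reproduce the documented
intervention effects (the 12-month awareness scenarios) at their published
magnitude — a per-day reading inflates annual incidence by roughly two
orders of magnitude.  The demographic rates are the exception: they derive
from life-expectancy arithmetic quoted per day
(`demographic_params()`), and are converted with
`per_day_to_per_month()`.  For the human mortality rate the package uses
$\mu_H = 1/(54.332\,\mathrm{y}) \approx 5.04\times 10^{-5}$ per day, the
value consistent with the recruitment/mortality balance
$\Lambda_H/\mu_H = 26{,}263{,}866$; an override is available.

## Numerical integration

Scenario runs use `deSolve::lsoda` (relative tolerance $10^{-8}$) on a
compiled right-hand side; the forward–backward sweep uses a fixed-step
classical Runge–Kutta on a uniform grid (default 1460 intervals over 12
months, a quarter-day step).  Transient negative excursions from the stiff
solver are clipped to zero inside the right-hand side; excursions beyond
$10^{-8}$ of the initial population abort the run.  Halving the fixed step
changes 12-month cumulative outcomes by well under 0.1%, and the snake
subsystem matches its logistic closed form to $10^{-6}$ relative — both
are asserted in the test suite.

## Calibration

`least_squares_fit()` minimises the weighted sum of squared residuals
between model-implied and observed cumulative series with L-BFGS-B from
multiple starts (bounds: $[0,1]$ for proportions, $[0,10]$ per month for
rates, order-of-magnitude windows for population-scale quantities).
`mcmc_sample()` then targets a Gaussian observation model on the
cumulative counts with per-series variances profiled out under a Jeffreys
prior, i.e. a log posterior $-\sum_s \tfrac{n}{2}\log \mathrm{SSR}_s$ on
the bound box, where $n$ counts the noisy month boundaries (the month-0
anchor row is shared by model and data and carries no likelihood weight).
The sampler is a random-walk Metropolis whose proposal covariance is
adapted to the empirical posterior covariance during burn-in
(Haario-style), with a scalar multiplier tuned to a 20–40% acceptance
fraction.  Convergence is monitored with the Gelman–Rubin potential scale
reduction factor $R_c = \sqrt{(n-1)/n + B/(nW)}$; the default verdict band
is $[0.9, 1.1]$.

The posteriors for this model are extremely tight (relative widths of
$10^{-4}$ and below at registry-like noise), which makes the sampler's
covariance adaptation essential: a bound-width random walk never reaches
workable acceptance rates at these scales.

## The synthetic registry generator

`generate_report()` emulates the registry tables: it perturbs the
model-implied monthly increments (Poisson "count" noise with variance
equal to the mean, the default) or the cumulative counts (Gaussian with
stated per-series SDs) and restores monotonicity by flooring increments at
zero or taking a running maximum.  The monotone restoration introduces a
small upward bias whenever the noise scale is comparable to the monthly
increments; the coverage experiments therefore use Gaussian SDs of 0.25%
of each series' range, for which truncation is a $>9\sigma$ event.  What
the generator does *not* emulate is under-reporting (known to exceed 70%
in the study region) or seasonality, so passing recovery tests show
internal consistency of the pipeline, not robustness to those features of
real registries.

## Optimal control

The objective $J = \int_0^T (B_1 I + B_2 D + \tfrac12(C_1 u_1^2 + C_2
u_2^2))\,dt$ is minimised over controls confined to $[0,1]$.  Costates
satisfy $\dot\lambda_x = -\partial H/\partial x$ with zero terminal
conditions (free terminal state); the force of infection is differentiated
as a state function, so every human compartment contributes through the
denominator $N_H + N_S$.  The analytic costate system is verified against
finite-difference Hamiltonian gradients at random points on every test
run — that check, not a printed formula, is the contract.  Controls are
characterised in closed form from $\partial H/\partial u_i = 0$ and
projected onto the box; the solver is the forward–backward sweep with
averaging relaxation $u \leftarrow (u_{\text{prev}} + u_{\text{char}})/2$,
converging when the relative $\ell_1$ change of states, costates and
controls drops below $10^{-4}$.  Strategy A forces $u_2 \equiv 0$,
strategy B forces $u_1 \equiv 0$ (the off control is genuinely off, not
held at a baseline level), and strategy C frees both.

## Cost-effectiveness

`discounted_control_cost()` integrates the published cost integrand
exactly as printed — including the adverse-reaction terms $\alpha_1 V_E +
\alpha_2 V_L$ that enter without a unit-cost coefficient (read as
management costs of US$1 per person-month) — discounted at 5% per year
converted to per month.  A corrected variant costing the treatment inflow
$C_2 u_2 \tau I$ is available via `cea_config(cost_model = "inflow")`.
ICER analysis follows the sequential walk used in the source analysis:
strategies in given order, the first carrying its absolute
cost-effectiveness ratio, each later one incremental against its
predecessor; a strategy whose incremental ICER exceeds its predecessor's
is dominated and removed, and the table is recomputed until stable.  A
separate `ce_frontier()` implements the textbook extended-dominance
frontier (equivalent to the lower convex hull of (effect, cost) anchored
at do-nothing), which the tests verify against a brute-force oracle.
Deaths averted convert to DALYs at 23.41 discounted DALYs per premature
death, and ICERs are classified against 1x/3x GDP-per-capita thresholds
(boundaries assigned upward).

## Known limitations and reproduction notes

The published scenario tables are only partially reproducible from the
printed inputs, and the package does not force agreement where the
arithmetic cannot support it:

* The 12-month awareness scenarios reproduce the published *envenomings
  averted* within 5% under the conventions above.  The published *deaths*
  and *disability averted* columns imply a per-case death fraction of
  about 1.05%, four times what the printed late-death rate $\delta_2 =
  4.26\times10^{-4}$ can generate (0.26%); no single-parameter reading we
  tried reproduces all columns at once, so the package reports what the
  printed parameters actually yield.
* The published early-treatment deaths-averted figures (296/918/1146 for
  k = 10/50/90%) have a saturating shape in $k$ that the model structure
  cannot produce (averted deaths are necessarily near-linear in $k$ here).
* The broadcast-media cost line items sum to US$519,264.46, not the
  printed US$444,562.66 subtotal; `awareness_budget()` sums the items.
* Optimal-control costs and effects are grid- and convention-sensitive;
  the package asserts solver *properties* (gradient checks, dominance of
  the converged policy over corner and random constant policies, the
  published switching pattern) rather than printed cost figures.

Test-suite problem sizes: coverage experiments use 20 synthetic registries
of 21 months with 2 chains x (1500 burn-in + 2500 kept) iterations; the
reduced MCMC reference budget is 4 chains x (5000 + 5000); sweep grids use
1460 intervals over 12 months.  Each choice is stated next to the test
that uses it.
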