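---
title: "Value trade-offs between consumption and health: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Value trade-offs between consumption and health}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qalyvto)
```

## The problem

Health plans deciding whether to add a new medical technology to their
formulary compare its incremental cost-effectiveness ratio (ICER, money per
QALY gained) against a willingness-to-pay (WTP) threshold. That threshold is
itself a *value trade-off*: the amount of consumption (money) a decision
maker gives up per unit of health gain while remaining indifferent. This
package implements two standard ways of deriving that trade-off from first
principles and the machinery to compare them:

1. a **multi-attribute utility (MAUT/MCDA)** model: a two-attribute
   multiplicative value function over consumption and QALY gain, with
   weights elicited as indifference probabilities;
2. an **expected-utility (ACEA)** model: a healthy enrollee facing future
   disease, insured at an actuarially fair premium, whose maximum WTP is
   pinned down by indifference between reimbursement and the status quo.

Both frameworks predict how the trade-off moves with income, the cost of
the technology, and the severity of disease; the package verifies those
comparative statics numerically and measures whether the two frameworks
move together — they do when health and consumption are complements or
independent, and can disagree when they are substitutes.

## The MAUT model

Single-attribute utilities $u^c(c)$, $u^h(h)$ are monotone and normalized
to $[0,1]$ over pre-determined ranges: consumption from $0$ to the
well-state income, health as QALY gain from $0$ (status quo of the sick) to
full cure $h^w - h^s$. Three families are provided (`utility_curve()`):
linear (risk neutral), power with exponent $\rho \in (0,1]$, and
exponential with rate $a > 0$ (constant absolute risk aversion $a$). The
families are an implementation choice — any monotone normalized curve is
admissible in the theory — selected because they are the standard
one-parameter shapes spanning risk neutrality to pronounced risk aversion,
and because both are normalized *by construction*, so the endpoint
conditions hold to machine precision rather than by numerical calibration.
A logarithmic family is deliberately excluded: it is undefined at a zero
consumption floor, which the elicitation ranges here include.

With mutual utility independence the bivariate value function is
multiplicative,
$$V(c,h) = k_c u^c(c) + k_h u^h(h) + K k_c k_h u^c(c) u^h(h), \qquad
K = \frac{1 - k_c - k_h}{k_c k_h},$$
with scaling constants $k_c, k_h \in (0,1]$ elicited as indifference
probabilities against a best/worst-corner lottery
(`elicit_scaling_constants()`; `simulate_elicitation()` inverts the task
and is used as a round-trip test). $K$'s sign tracks $1 - k_c - k_h$:
positive means the attributes are complements, zero additive, negative
substitutes. Substitutes models are constructible but flagged with a
warning, because the monotone trade-off properties below hold only for
$K \ge 0$.

The value trade-off is the indifference-curve slope obtained by setting
$dV = 0$:
$$\frac{dc}{dh} = \frac{u^{h\prime}}{u^{c\prime}}
\cdot \frac{k_h + (1-k_c-k_h)u^c(c)}{k_c + (1-k_c-k_h)u^h(h)},$$
reported by `maut_vto()` as a positive money-per-QALY magnitude (the sign
convention: it is the *decrease* in consumption compensating a unit gain in
health). The default evaluation point is the status quo — maximum
consumption, zero QALY gain — and any interior point is accepted. For
$k \in (0,1)$ the bracket terms are strictly positive; they can reach zero
only in the degenerate corner $k_j = 1$ with the opposing utility at its
maximum, which is rejected as an invalid trade-off point rather than
returned as an infinite or negative trade-off.

`trace_indifference_curve()` recovers the same curves numerically:
for each health level it solves $V(c,h) = \bar v$ for $c$ by bisection
(`uniroot`) on the consumption range — monotonicity of $V$ in $c$
guarantees a unique bracketed root — then polishes with two or three
Newton steps using the analytic $\partial V/\partial c$, driving the
residual in $V$ below $10^{-10}$ (typically to machine precision). Levels
unattainable at a given health level are reported as `NA`, never
extrapolated. The secant slope of the traced curve is the independent
oracle against which the closed-form `maut_vto()` is tested (relative
agreement $10^{-5}$ at a symmetric step of $10^{-4}$ of the health range).

## The ACEA model

Preferences are a bivariate state utility $u(c,h)$ (`bivariate_utility()`),
the same function in both states of the world. Families:

* `additive`: $u = g(c) + \beta m(h)$, additively separable
  ($u_{ch} = 0$);
* `interaction`: $u = g(c) + \beta m(h) + \theta\, g(c) m(h)$, where
  $\mathrm{sign}(u_{ch}) = \mathrm{sign}(\theta)$;
* `custom`: any user function, with central finite-difference partials
  (relative step $10^{-5}$, scaled to the argument).

$g$ and $m$ are CRRA-style indices with curvatures $r_c$ and $r_h$
($0$ linear, $1$ logarithmic). Giving the *health* argument its own
curvature matters: with $r_h > 0$ the marginal utility of health rises as
the sick-state health level falls, which is the channel through which
severity raises the ACEA trade-off even under additive separability.

Without reimbursement (NR) the enrollee consumes income in each state:
$E(u)_{NR} = \pi u(y^s, h^s) + (1-\pi) u(y^w, h^w)$. With reimbursement
(R), the plan covers $I(p) = \text{coverage}\cdot p$ at the actuarially
fair premium $\pi I(p)$; the sick state bears the co-payment
$p - (1-\pi)I(p)$, and the enrollee pays $V$ over and above covered
expenses in both states, so
$\Sigma^s = p - (1-\pi)I(p) + V$ and $\Sigma^w = \pi I(p) + V$,
and health improves to $h^s + dh^s$ in the sick state.

`solve_max_wtp()` finds the $V^*$ equating the two expected utilities.
Because $E(u)_R$ is strictly decreasing in $V$, the root is unique; the
solver brackets it (expanding the lower bound geometrically when the
technology is not worth its premium, i.e. $V^* < 0$, which is returned
flagged rather than clamped), applies `uniroot`, and Newton-polishes with
the analytic derivative
$-(\pi u_c^s + (1-\pi)u_c^w)$ until the expected-utility gap is below
$10^{-10}$. Payments that exhaust consumption in either state are an
error with diagnostics, not a silent boundary solution.

The closed-form trade-offs evaluated at the status quo are
$$-\frac{dc^s}{dh^s} = \frac{\pi u_h^s}{\pi u_c^s + \gamma(1-\pi)u_c^w}
\quad\text{(enrollee)}, \qquad
\frac{dp}{dh^s} = \frac{u_h^s}{\pi u_c^s + \gamma(1-\pi)u_c^w}
\quad\text{(payer)},$$
implemented independently in `acea_vto()` and `acea_pvto()`; their exact
ratio $\pi$ is a test, not a definition. $\gamma \ge 1$ weights the
well-state marginal utility of income (WTP can be larger in the well
state because income is larger there); it is a free input with default 1 —
the theory motivates $\gamma$ but fixes no functional link to the income
ratio, so the package does not invent one. The formulas default to
status-quo incomes ($c^s = y^s$, $c^w = y^w$); an evaluation-point switch
(`at = "premium_adjusted"`) substitutes premium- and co-payment-adjusted
consumption, which is how a costlier technology lowers the trade-off
(Property 1) — the printed formulas themselves do not contain $p$.

`complementarity_class()` classifies health and consumption at a point as
Hicksian q-complements, q-substitutes or independent by the sign of
$u_{ch}$, with a dead band of $10^{-8}$ for the independent verdict
(finite-difference cross-partials of custom utilities are noisy at the
$10^{-10}$ level; the dead band absorbs that without misclassifying any
parametric family).

## Comparative statics and concordance

`comparative_statics()` sweeps one factor and checks the predicted
monotone direction of the trade-off:

| factor | channel | predicted direction |
|---|---|---|
| technology cost | premium reduces consumption | non-increasing |
| income | higher consumption | non-decreasing |
| severity | lower health level | larger for more severe |

On the MAUT side the consumption evaluation point is
`income − π·coverage·p`; severity levels are positions on the health-gain
scale (lower = further from full health = more severe). On the ACEA side
income sweeps scale both state incomes proportionally, cost sweeps use
premium-adjusted evaluation, and severity sweeps lower $h^s$. The
directions are guaranteed under the stated sufficient conditions —
$K \ge 0$, $u_{ch} \ge 0$, concave utilities — and the package asserts
them only there; adjacent-pair reversals smaller than $10^{-9}$ of the
value scale are treated as floating-point ties. Infeasible sweep levels
are excluded and recorded. Risk-neutral special cases (linear curves with
$k_c + k_h = 1$; linear additive $u$) yield constant trade-offs, checked
to a coefficient of variation below $10^{-10}$.

`concordance()` runs both models on a shared scenario and records, for
each perturbation (income $+10\%$, cost $+10\%$, one severity step by
default), whether the two trade-offs move in the same direction. Two
measurement conventions deserve explanation, since the design here was
genuinely open:

* **Fixed measurement frame.** The MAUT attribute ranges are anchored once
  per comparison (consumption range covering all incomes contemplated,
  health range anchored at the most severe state contemplated) and *not*
  re-derived per perturbation. Re-deriving $h^* = h^w - h^s$ at each
  severity level would rescale $u^h$ itself — the marginal utility per
  QALY falls as $1/h^*$ — so the measured trade-off would drop with
  severity as a pure renormalization artifact, contradicting the
  severity property both frameworks predict. Holding the frame fixed
  separates a change in the *object measured* (the patient's position)
  from a change in the *measuring stick* (the normalization range).
* **Severity as a lower health evaluation point.** One severity step
  lowers the MAUT health evaluation point and the ACEA $h^s$ by the same
  $\delta$ (default 0.1 QALY). The base MAUT point sits
  $(\text{steps}+1)\delta$ above the range floor so that power-family
  curves, whose marginal utility diverges at the floor, are never
  evaluated exactly there. The alternative severity channel — raising
  $k_h$ for more severe disease — is real but has no canonical functional
  form; it is left to the user (pass adjusted constants) rather than
  hard-coded, so that both frameworks see the same primitive change.

Under complements or independence on both sides all signs agree;
`find_discordant_example()` searches random substitutes parameterizations
($k_c + k_h > 1$, hence $K<0$, against $u_{ch} > 0$) and returns a
flagged disagreement, demonstrating the inconsistency that negative
attribute interaction can induce in formulary decisions.

`formulary_decision()` applies the threshold rule: funded iff
ICER $\le$ threshold. Equality means indifference; the tie resolves to
funding by default (configurable), and the rule is scale-invariant.

## Scenario configuration and fixtures

Scenarios are YAML files (`load_scenario_config()`) with sections for
ranges, curves, scaling constants *or* elicitation probabilities
(mutually exclusive), the health scenario, the insurance plan and the
bivariate utility; validation collects every violation, not just the
first. `generate_fixtures()` draws random feasible scenarios from
documented parameter boxes (scaling constants in $[0.05, 0.95]$, disease
probability in $[0.01, 0.5]$, well-state income in $[10^4, 10^5]$, health
levels in $(0,1]$), deterministically for a given seed. Exponential-curve
rates are drawn relative to the attribute range (rate × range moderate),
since a fixed absolute rate on a $10^5$ money range would underflow the
marginal utility to zero; likewise, random interaction coefficients
$\theta$ are bounded as a share of the direct health weight at the top
income, so marginal utilities stay positive over the whole income box. These boxes emulate the magnitudes typical of
insured working-age populations (annual incomes in tens of thousands,
technology costs up to ~20% of income, QALY gains below one); they do not
emulate estimation noise, elicitation error, or preference heterogeneity
within a plan — passing property sweeps on these fixtures shows the
*models* behave as the theory predicts, not that any elicited real-world
weights will.

## Numerical choices, at a glance

* Root-finding: bisection brackets plus analytic-derivative Newton
  polishing; residual tolerances $10^{-10}$ in the objective (indifference
  level or expected-utility gap).
* Trade-off oracle agreement: relative $10^{-5}$, secant step $10^{-4}$ of
  the health range, evaluation points kept in the middle of the box.
* Monotonicity ties: $10^{-9}$ of the value scale.
* Complementarity dead band: $|u_{ch}| \le 10^{-8}$.
* Finite differences (custom utilities): central, relative step $10^{-5}$.
* Degenerate inputs (empty ranges, zero scaling constants, non-positive
  marginal utilities, consumption-exhausting payments, unattainable
  indifference levels) are errors or recorded exclusions — never silently
  patched values.

Test-suite problem sizes (200 random models for normalization and oracle
checks, 100 for the solver and elicitation round trips, 50 for the
small-gain limit) keep the full suite under ~10 seconds while exercising
all families and constraint regimes.

## Limitations

* The health attribute is a given scalar QALY (or any unidimensional
  index) gain; the aggregation of novel value elements into that scalar is
  out of scope.
* Partial coverage is handled by the numeric solver only; no closed-form
  trade-off is asserted for $I'(p) < 1$.
* $\gamma$ is an input, not estimated.
* The substitutes counterexample is an existence demonstration found by
  search, not a characterization of when disagreement occurs.
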