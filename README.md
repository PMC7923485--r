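# qalyvto

Cost-per-QALY value trade-offs from multi-attribute utility and
expected-utility models.

## What this is for

Health plans and HTA bodies decide whether to fund a new medical
technology by comparing its incremental cost-effectiveness ratio (ICER,
money per QALY gained) with a willingness-to-pay (WTP) threshold. That
threshold is a *value trade-off*: the amount of consumption a decision
maker gives up per unit of health gain while staying indifferent. This
package, aimed at health economists and decision modellers, derives that
trade-off from first principles in two frameworks and analyses when they
agree:

**MCDA / multi-attribute utility.** Over consumption `c` and QALY gain
`h`, with normalized single-attribute utilities and scaling constants
elicited as indifference probabilities, the multiplicative value function
is

    V(c,h) = k_c u^c(c) + k_h u^h(h) + K k_c k_h u^c(c) u^h(h),
    K = (1 - k_c - k_h) / (k_c k_h)

and the trade-off is the indifference-curve slope

    dc/dh = (u^h' / u^c') * [k_h + (1-k_c-k_h) u^c(c)]
                          / [k_c + (1-k_c-k_h) u^h(h)].

**ACEA / expected utility.** A healthy enrollee faces disease with
probability `π`; an insurance plan covers `I(p)` of the technology cost
`p` at the actuarially fair premium `πI(p)`. The maximum extra payment
`V*` solves the indifference condition `E(u)_R(V*) = E(u)_NR`, and the
closed-form trade-offs at the status quo are

    enrollee:  -dc^s/dh^s = π u_h^s / (π u_c^s + γ(1-π) u_c^w)
    payer:      dp/dh^s  =   u_h^s / (π u_c^s + γ(1-π) u_c^w)

The package verifies numerically that both trade-offs fall with the
technology cost, rise with income and rise with severity of disease
(under complementarity, `K ≥ 0` / `u_ch ≥ 0`, and concavity), and that
the two frameworks move in the same direction under those conditions —
with a searchable counterexample when health and consumption are
substitutes.

## Worked example

Using the example scenario shipped with the package (moderately severe
disease, `π = 0.1`, incomes 45k/50k, 0.25 QALY gain, technology cost
2000 with complete coverage, complementary preferences on both sides):

```r
library(qalyvto)
cfg <- load_scenario_config(system.file("extdata", "scenario.yaml",
                                        package = "qalyvto"))
m <- as_maut_model(cfg)
summary(m)
#> MAUT scaling constants: k_c = 0.3  k_h = 0.5  K = 1.333333
#> Attribute interaction: complements (K > 0)
#> Value trade-off near the status quo (maximum consumption, gain 0.005):
#> 1317608 money per QALY

ai <- as_acea_inputs(cfg)
solve_max_wtp(ai$u, ai$scenario, ai$plan)
#> Maximum willingness to pay (indifference with status quo)
#>   V* = 271.1552
#>   state expenses: sigma_s = 471.1552  sigma_w = 471.1552
#>   residual expected-utility gap: 0

acea_vto(ai$u, ai$scenario)   # 2107.2 money per QALY (enrollee)
acea_pvto(ai$u, ai$scenario)  # 21071.8 money per QALY (payer)

concordance(m, ai$u, ai$scenario, ai$plan)
#> MAUT/ACEA concordance: 3/3 sign agreements (base trade-offs 350196.9 / 2098.348)
#>     factor maut_vto acea_vto maut_sign acea_sign agree
#> 1   income 365315.2 2316.233         1         1  TRUE
#> 2     cost 350135.3 2097.465        -1        -1  TRUE
#> 3 severity 448592.9 2346.402         1         1  TRUE

formulary_decision(icer = 8000, threshold = acea_pvto(ai$u, ai$scenario))
#> Formulary decision: ICER 8000 vs threshold 21071.84 -> FUND
```

Reading the numbers: the enrollee would pay up to 271 over and above
covered expenses for reimbursement of this technology (total state
expenses 471 = fair premium 200 + 271). The payer's trade-off says a cost
increase of up to ~21,000 per additional QALY would still be accepted, so
a technology with an ICER of 8,000 is funded. Both frameworks' trade-offs
move up with income and severity and down with cost — full sign
concordance, as predicted when health and consumption are complements.
The MAUT trade-off is on a different scale than the ACEA one (hundreds of
thousands vs thousands): it is measured against the normalized attribute
box near zero gain, where concave health utilities make the first QALY
sliver extremely valuable; the comparison exercise concerns directions of
change, not levels.

A thin command-line wrapper is installed at `inst/cli/vto.R`
(subcommands `maut`, `acea`, `properties`, `compare`, `fixtures`), e.g.

```sh
Rscript inst/cli/vto.R compare --config inst/extdata/scenario.yaml
Rscript inst/cli/vto.R fixtures --n 5 --seed 42 --constraints complements_only
```

The methods vignette (`vignettes/value-trade-offs.Rmd`) documents the
models, the measurement conventions behind the concordance analysis, and
all numerical tolerances.

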