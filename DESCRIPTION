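Package: qalyvto
Title: Cost-per-QALY Value Trade-Offs from Multi-Attribute Utility and
    Expected-Utility Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving and analysing cost-per-QALY value trade-offs
    (willingness-to-pay thresholds) in health technology assessment from two
    preference frameworks: a two-attribute multiplicative multi-attribute
    utility (MAUT/MCDA) model over consumption and health gain, and an
    expected-utility model of an insured enrollee facing future disease
    (augmented cost-effectiveness analysis, ACEA). Provides normalized
    single-attribute utility curves, scaling-constant elicitation via
    indifference probabilities, closed-form and numerically traced
    indifference-curve trade-offs, a maximum willingness-to-pay solver based
    on the indifference condition between reimbursement and status quo,
    payer trade-offs, Hicksian complementarity classification, systematic
    numerical verification of comparative-statics properties (income,
    technology cost, severity of disease), concordance analysis between the
    two frameworks, and an ICER-threshold formulary decision rule.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
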