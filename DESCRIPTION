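Package: rnaidose
Title: Delayed RNAi Dose-Effect Modeling, Hopf Bifurcation Analysis and
    siRNA Dosage Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a two-stage (mRNA/protein) gene-expression model in
    which RNA interference adds a Hill-saturating mRNA degradation term, with
    a transcriptional-silencing delay and a nuclear-export delay. Provides a
    fixed-step method-of-steps integrator for the delay system, closed-form
    and root-finding stability analysis of the transcendental characteristic
    equation (thresholds, crossing frequency, critical delay and dosage,
    regime classification, transversality), approximate and measured
    limit-cycle periods, forward sensitivity equations and relative
    sensitivities of the oscillation's amplitude and period, and adjoint
    (costate) machinery for selecting the siRNA dosage that minimizes a
    combined siRNA-expenditure and protein-accumulation cost.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
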