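Package: dioxinrecon
Title: Reconstruction of Historical PCDD/F Emissions from Waste Incinerators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for reconstructing historical emissions of polychlorinated
    dibenzo-p-dioxins and dibenzofurans (PCDD/Fs) from municipal solid waste
    incinerators. Propagates phase-resolved congener profiles through air
    pollution control devices via concentration-based removal efficiencies,
    estimates furnace-side generation with a two-step first-order
    formation-decomposition kinetic model, assembles annual stack-emission
    timelines under device scenarios, converts emissions into residual soil
    amounts and toxic equivalents (TEQ) with half-life uncertainty bands, and
    attributes output variance to inputs by Latin hypercube sampling with
    normalized squared Spearman rank correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lhs,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    jsonlite
Config/testthat/edition: 3
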