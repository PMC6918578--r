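Package: methylopath
Title: In Silico Evaluation of Methanol and Formaldehyde Assimilation
    Pathways in Oleaginous Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based and thermodynamic evaluation of synthetic
    methanol utilisation in Yarrowia lipolytica. Reconciles literature
    formation data for the formaldehyde/methylene-glycol pool, extrapolates
    reaction Gibbs energies over temperature and predicts the equilibrium
    formaldehyde concentration of the alcohol-dehydrogenase reaction;
    extends a stoichiometric model with the RuMP, XuMP and serine-cycle
    formaldehyde assimilation pathways and compares growth and
    triacylglycerol objectives by flux balance analysis; and triages
    hexulose-phosphate-synthase candidate sequences by global-identity
    clustering and neighbour-joining trees. Ships a reduced yeast-like
    core model and synthetic-data generators so that every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
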