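Package: upfinder
Title: Identification of Gene Overexpression Targets in Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for up-regulated pathway analysis (UPA) of genome-scale
    metabolic models. Given an SBML model and a target metabolite, the package
    compares flux balance analysis (FBA) solutions of the wild-type network and
    of the theoretical-maximum-yield network, identifies reactions whose flux
    must increase to reach maximum production, re-verifies each candidate by
    fixing it at its optimum flux and re-simulating growth-coupled product
    yield, and returns a ranked table of overexpression targets annotated with
    wild-type flux, optimum flux, up-regulation Ratio, re-verified Yield, the
    associated genes, and Ratio-level metabolic module labels. Includes an SBML
    reader/writer (Level 3 fbc and Level 2 note dialects), a self-contained
    linear-programming engine with a parsimonious-FBA option, generators for
    small toy networks with analytically known optima, an exact
    vertex-enumeration oracle for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
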