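Package: basicpathways
Title: Basic-Pathway Decomposition of Steady-State Metabolic Networks in
    Growing Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs nonnegative linear bases ("basic pathways") of the
    stoichiometric null space for metabolic networks in exponentially
    growing cells, using exact rational arithmetic throughout. Growth
    dilution contributes one drain pseudo-reaction per metabolite, which
    gives the null space a closed-form fundamental basis; a
    singleton-cost-guided column-operation elimination turns that basis
    into a nonnegative one in polynomial time. Includes degenerate-network
    reduction, pathway decomposition in basic-pathway coordinates,
    coefficient lower bounds for singleton-deficient bases, an extreme-ray
    rank test with a brute-force enumeration oracle, a built-in coupled
    glycolysis/TCA-cycle case model, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
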