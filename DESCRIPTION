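Package: chemmix
Title: Shared-Target and Enrichment Analysis for Chemical Mixtures
Version: 0.1.0
Authors@R: person("chemmix", "maintainers", email = "maintainers@chemmix.invalid",
    role = c("aut", "cre"))
Description: Analyzes potential interaction effects of chemical mixtures
    (2-4 chemicals) from chemogenomics data. Reads STITCH-shaped
    chemical-protein interaction links, resolves chemicals by name or CAS
    number, extracts confidence-filtered target gene sets, performs
    hypergeometric over-representation analysis against GMT annotation
    catalogs (GO, pathway, disease namespaces) with Benjamini-Hochberg
    correction, partitions targets and enriched terms into Venn regions,
    combines per-chemical adjusted p-values of shared terms into a product
    joint p-value, and computes union-based overall-effect enrichment.
    Includes a seeded synthetic-data generator so the full pipeline is
    testable offline, plus a command-line interface and deterministic
    CSV/JSON report writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
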