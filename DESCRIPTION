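Package: hostspec
Title: Transmission Routes and Cophylogeny of Host-Specific Symbionts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how horizontal conspecific contact can maintain
    host-specific ectosymbionts on a brood-parasitic host that lacks
    parental care. Classifies symbiont occurrence records into
    host-specificity categories, tabulates prevalence and co-occurrence,
    and estimates the conspecific-to-interspecific transmission-rate
    ratio with assignment bounds for symbionts of undetermined route.
    Also computes Kimura two-parameter distances with gene-flow calls
    and barcode-gap OTU delimitation, reconciles symbiont and host
    phylogenies by event-based maximum parsimony (codivergence,
    duplication, host switch, loss), and provides simulators for
    occurrence, sequence and cophylogeny data so every stage can be
    validated by parameter and event recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
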