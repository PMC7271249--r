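Package: ppiref
Title: Evidence-Scored Protein-Protein Interaction Reference Networks
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds an evidence-scored reference network of mouse
    protein-protein interactions from PSI-MITAB records. Aggregates
    per-pair evidence (studies, detection techniques, cross-species
    interolog support) and converts it into a saturating confidence
    score; annotates interactions with ontology terms by descendant
    closure and with tissues by joint TPM presence calls; answers
    protein, network and screen-annotation queries with confidence,
    type, tissue and functional filters; and infers edge directionality
    from shortest paths between receptors and transcription factors.
    Includes a seeded synthetic-fixture generator and a packaged Hippo
    pathway example.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
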