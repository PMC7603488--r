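Package: proteoflux
Title: Ancestral Gene-Content Flux by Gene-Tree/Species-Tree Reconciliation
Version: 0.1.0
Authors@R:
    person("proteoflux", "developers", email = "proteoflux@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing the history of gene duplication, loss,
    intra-set lateral transfer and origination across a prokaryotic phylogeny.
    Implements minimum-cost undated duplication-transfer-loss reconciliation of
    gene trees against a rooted species tree with completeness-aware loss
    costs, per-branch event aggregation and ancestral proteome-content
    reconstruction, completeness-corrected fate analysis of originating gene
    families, Markov-clustering protein families with single-copy core-marker
    selection and BLOSUM62 medoids, average amino acid identity (AAI) taxonomy
    with phylogenetic-distance rank assignment, homology-hit filtering with
    proteome-novelty and origination-source classification, and a gene-family
    birth-death-transfer simulator with exact per-branch event ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
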