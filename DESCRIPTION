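Package: phyloHET
Title: Hybrid Taxon Detection in Multilocus Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects taxa of hybrid origin in multilocus DNA datasets.
    Implements the homoplasy excess test (taxon-removal jack-knife with
    per-node bootstrap-support null distributions and a Tukey upper-fence
    outlier rule), algorithmic detection of cytonuclear discordance between
    nuclear and mitochondrial consensus trees, and maternal/paternal parent
    assignment of putative hybrids from mitochondrial markers and cloned
    nuclear alleles.  Includes a synthetic multilocus data generator with
    known ground truth (mosaic and F1 hybrids, cytonuclear transfers) so the
    whole pipeline can be validated end to end, plus desk-scale tree
    inference (distances, neighbour joining, nonparametric bootstrap,
    extended majority-rule consensus) behind a pluggable backend contract.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    seqinr,
    phytools,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
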