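Package: phyloassembly
Title: Phylogenetic Null Models and Neutral Theory for Microbial Community Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the ecological processes that assemble microbial
    communities from an OTU count table, a rooted phylogeny and sample
    metadata. Implements phylogenetic null models (NTI, beta-MNTD/beta-NTI
    with tip-label randomizations), the Bray-Curtis-based Raup-Crick null
    (RCbray), the five-process assembly partition (variable and homogeneous
    selection, dispersal limitation, homogenizing dispersal, drift), Sloan's
    neutral community model fit, Preston log-normal species-abundance fits
    with AIC model comparison, taxonomic and phylogenetic alpha and beta
    diversity, and Mantel / partial Mantel tests against environmental and
    geographic distances. A synthetic-data module generates communities
    under known assembly regimes (neutral immigration, phylogenetically
    structured selection, patch-limited dispersal) so the whole pipeline can
    be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    vegan,
    picante,
    geosphere,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    phyloseq,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
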