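Package: crossBN
Title: Causal Bayesian Network Reconstruction from Segregating Crosses
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrative reconstruction of directed causal networks among
    gene-expression and metabolite traits measured in a segregating
    population (e.g. a haploid yeast cross). Provides single-marker LOD
    scanning with permutation thresholds and trans-hotspot detection, the
    genotype-anchored three-model causality test with BIC model selection
    and bootstrap reliabilities, construction of structure priors from
    genetic data, transcription-factor binding sites, protein complexes
    and KEGG reaction graphs, stochastic score-based Bayesian-network
    structure search with consensus model averaging and cycle removal,
    subnetwork extraction, and a synthetic-cross generator so that every
    stage can be exercised against a known ground-truth network.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, igraph, xml2, withr
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
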