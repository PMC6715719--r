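Package: methdyn
Title: Brain Methylome Dynamics: Bipolar Loci, Co-Methylation Modules and
    Permutation-FDR Differential Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for bisulfite-sequencing methylomes of mixed
    neural cell populations. Detects bipolar methylated loci from read-level
    methylation patterns (reads splitting into completely methylated and
    completely unmethylated classes), discovers co-methylated locus modules
    across developmental stages, calls differentially methylated sites and
    regions with a Fisher exact test, a sequential permutation p-value and a
    histogram-based estimate of the number of true null hypotheses, and
    integrates ChIP-seq peak sets with methylomes (methylation-dynamics
    classification, peak overlap accounting, nearest-peak distances, site
    density profiles and interval enrichment). Includes seeded synthetic-data
    generators emulating neuron/glia mixtures, developmental trajectories,
    bisulfite non-conversion noise, unmethylated spike-in controls and
    planted knockout hypermethylation, so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
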