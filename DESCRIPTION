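Package: hadalrange
Title: Population Genetics and Depth-Envelope Range Projection for
    Deep-Sea Taxa
Version: 0.1.0
Authors@R:
    person("Paige", "Rever", email = "prever@example.org", role = c("aut", "cre"))
Description: Tools for analysing the distribution and genetic structure of
    cosmopolitan deep-sea species from single-locus sequence data and
    occurrence records. Computes per-locus diversity statistics (haplotype
    and nucleotide diversity, segregating sites, Tajima's D with a
    beta-approximation significance test), uncorrected and JC69/F81
    corrected pairwise distance matrices, statistical-parsimony haplotype
    networks with a Monte-Carlo connection limit, a single-linkage
    barcode-gap partition sweep for species delimitation, and a
    depth-envelope habitat projection over gridded bathymetry that yields
    per-ocean-basin suitable-area percentages. Includes a neutral
    coalescent simulator and analytic bathymetry generators so every stage
    is testable offline, and a pipeline driver with reproducible run
    manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
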