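Package: epiplast
Title: Individual-Based Simulation of Phenotypic Plasticity via
    Stress-Sensitive Epigenetic Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based simulator of phenotypic plasticity arising from
    stress-sensitive epigenetic activation and silencing of additive loci.
    Phenotypes are encoded by multilocus diploid (or haploid) genotypes whose
    plastic loci flip activation state during a finite developmental period at
    a rate that increases with the mismatch between the phenotype and the
    environment, producing trial-and-error developmental learning. The package
    implements selection with density-dependent fitness, Poisson reproduction,
    recombination and allelic mutation under constant, periodic and directional
    environmental change; the heritable sensitivity trait controlling the
    epimutation rate can itself evolve. Per-generation summaries include mean
    population stress, genetic load and the developmental phenotype-variance
    ratio diagnosing canalization and the release of cryptic genetic variation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
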