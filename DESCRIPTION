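Package: vcgsim
Title: Stochastic Simulation of Virtual Circular Genome Replication in
    Protocells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates nonenzymatic RNA replication of a virtual circular
    genome inside a model protocell. An ensemble of oligonucleotides mapping
    onto both strands of an abstract circular reference sequence is maintained
    on a length-versus-abundance gradient and replicated through
    denature/anneal cycles that drive template-directed primer extension from
    imidazolium-bridged dinucleotides, templated ligation, and dinucleotide
    primed initiation, together with activation/hydrolysis turnover, strand
    cleavage fates, chain termination, dead-end duplex formation, and binomial
    segregation of the ensemble at protocell division. Includes closed-form
    calculators for gradient arithmetic, copy numbers, segregation loss,
    melting-stability/concentration coupling, and ribozyme flux, plus an
    error-threshold experiment harness.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
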