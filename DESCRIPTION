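Package: crisprdyn
Title: Eco-Evolutionary Dynamics of Constitutive and Inducible Phage Defence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and stochastic simulation of a five-compartment
    bacteria-phage model in which sensitive hosts acquire either constitutive
    surface-based resistance (receptor mutation, replication-coupled) or
    inducible CRISPR-Cas immunity (infection-coupled spacer acquisition),
    under serial-transfer batch culture. Provides population-genetic
    diagnostics (genotype frequencies, two-locus linkage disequilibrium,
    per-allele selection coefficients and their interference), factorial
    experiment designs over phage dose, carrying capacity and inoculum size,
    a synthetic clone-phenotyping data generator emulating two-phage streak
    assays, and maximum-likelihood parameter inference from clone tables
    under a multinomial observation model.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
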