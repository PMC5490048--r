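Package: eusocia
Title: Inclusive Fitness, Sex Ratios and the Evolution of Helping in
    Partially Bivoltine Insects
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Class-structured matrix population models for partially
    bivoltine insect life cycles (female hibernation and larval diapause)
    under haplodiploid or diploid genetics and monogamous, serially
    monogamous or polyandrous mating.  Computes stable class distributions,
    class-specific reproductive values from gene-flow matrices, selection
    gradients for brood sex ratios and helping tendency, eusociality
    thresholds (the minimal helper efficiency B at which helping is
    favoured), adaptive-dynamics integration of the coevolution of sex
    ratios and helping, and a matching stochastic individual-based
    simulator with three continuous-allele loci.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
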