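Package: coaltree
Title: Coalescence-Time Inference from Rooted Gene Trees under the
    Infinite-Sites Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the time to the most recent common ancestor (TMRCA)
    of a sample of aligned DNA sequences under Kingman's coalescent and the
    infinite-sites mutation model.  From the segregating sites of the sample
    the package constructs all s+1 rooted gene trees compatible with the
    data (perfect-phylogeny enumeration via root repositioning on the
    unrooted gene tree), and computes a Monte-Carlo posterior-mean estimate
    of the TMRCA by simulating coalescent waiting times, allocating them
    backward onto each rooted tree with leaf-count-proportional weights, and
    distributing the observed mutations multinomially across the coalescent
    intervals spanned by each branch segment.  Closed-form predata moments,
    the Watterson ancestor probability, conditional posterior means, and an
    infinite-sites coalescent simulator with known ground truth are
    included, together with the classic Nuu-Chah-Nulth mitochondrial
    control-region lineage table as a packaged example dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
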