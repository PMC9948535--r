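Package: helixknot
Title: Chiral Worm-Like Chains and the Topological Chirality of Polymer Knots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Monte Carlo simulation of isolated helical polymers modelled as
    worm-like chains with a short-range chiral coupling and hard-core
    excluded volume, together with a self-contained knot-analysis stack:
    deterministic chain closure, KMT reduction, planar diagram extraction
    with signed crossings, HOMFLY polynomial computation by skein recursion,
    and classification of knots by type and handedness. Helical order is
    quantified through the discrete chain torsion and the variance of the
    chiral energy; knot populations are aggregated into knotting and
    handedness probabilities with binomial errors, including a screening
    filter for tightly braided conformations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
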