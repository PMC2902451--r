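Package: rnagauss
Title: Alignment-Free Comparison of RNA Tertiary Structures with Gauss
    Integrals
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Represents the phosphorus-atom backbone of an RNA chain as a
    polygonal space curve and summarises its global shape by a
    30-dimensional descriptor: a backbone-length measure plus 29 Gauss
    integrals of orders one to three built from pairwise segment writhe.
    Descriptors are compared by Euclidean distance with empirical
    significance taken from a background distance distribution.  Tools are
    provided to build, update and scan single-file descriptor databases of
    RNA structures, to generate synthetic backbone curves with known
    topological properties, to evaluate classifications with ROC curves,
    and to drive everything from a command line.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
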