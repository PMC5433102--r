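Package: cnphylo
Title: Parsimony Phylogenies from Tumor Copy-Number Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maximum-parsimony evolutionary analysis of integer copy-number
    profiles under the segmental amplification/deletion event model. Computes
    the asymmetric event distance between two profiles by dynamic programming,
    solves the copy-number triplet (median) problem with a pseudo-polynomial
    dynamic program, and solves the copy-number tree problem -- a phylogeny
    whose leaves carry observed profiles, whose root is diploid and whose
    total event cost is minimum -- as an integer linear program over a
    supergraph of all full binary topologies. Includes a ground-truthed
    instance simulator, normalized Robinson-Foulds topology evaluation, a
    hardness-gadget encoder for binary-character parsimony instances, and
    exhaustive small-scale oracles used to validate every solver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: Python (>= 3.8) with scipy (>= 1.9) on the PATH, used as
    the mixed-integer programming backend (HiGHS via scipy.optimize.milp).
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
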