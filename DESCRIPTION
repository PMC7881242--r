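Package: planknet
Title: Discrete Bayesian Network Inference for Plankton Community Time Series
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Learns ecological dependency networks from discretized plankton
    abundance data. Provides zero/low/high discretization of zero-inflated
    count tables, contingency-test edge filtering, greedy hill-climbing
    structure search under a Bayesian-Dirichlet (BDeu) score with a parent
    limit, signed influence scores on ordinal conditional probability tables,
    bootstrap model averaging with consensus-network extraction, exact
    posterior queries, transposition of spatially inferred dependencies onto
    historic networks to reconstruct jellyfish abundance probabilities, and
    forced-edge naive-Bayes ranking of prey groups against an annual catch
    series. Includes a synthetic generator emulating Continuous Plankton
    Recorder style weekly count series and spatial station snapshots from a
    known ground-truth network.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tools, igraph, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: NetworkInference, GraphAndNetwork, TimeCourse, Bayesian
RoxygenNote: 7.3.3
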