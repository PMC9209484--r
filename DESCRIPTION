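Package: fvscreen
Title: Feedback Vertex Set Control Screening on Signed Biological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate cell-fate reprogramming interventions on a
    static signed regulatory network. Steady-state expression profiles
    (attractors) are estimated by signal flow analysis, a degree-normalized
    linear propagation scheme; feedback vertex sets -- node sets whose
    override is sufficient to steer a nonlinear system between its natural
    attractors -- are found by simulated annealing with an exact
    enumeration oracle for small networks; all 3^n override combinations on
    the control nodes are screened from the undesired phenotype's initial
    state; and the resulting attractors are filtered by a three-classifier
    majority vote against the k-means attractor landscape and by
    internal-marker expression-range criteria. Includes a synthetic fixture
    generator (planted-cycle networks, two-phenotype expression tables,
    noise injection) so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    cluster,
    e1071,
    randomForest,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
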