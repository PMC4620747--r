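Package: gdtarea
Title: Near-Optimal Computation of the Area Under the GDT Curve
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Protein model quality assessment by the area under the GDT
    (Global Distance Test) curve. Implements the polynomial-time
    near-optimal algorithm for the area under the Hubbard step function
    of a model against an experimental structure: epsilon-net
    discretization of rigid motions anchored at candidate radial pairs,
    an O(n log n) plane-sweep optimization of the rotation about the
    anchor axis, one-pass accumulation of all grid values H_i, and the
    Riemann-sum area estimate with its 4-epsilon guarantee. Also
    provides GDT_TS/GDT_HA scoring at fixed cutoffs, a brute-force
    subset-bottleneck oracle for tiny instances, deterministic synthetic
    structure-pair generators, C-alpha readers for PDB and plain-text
    coordinate tables, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
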