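Package: fiberopt
Title: Surrogate-Assisted Inverse Design of Doxorubicin-Loaded Electrospun Nanofibers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Machine-learning pipeline for formulation optimization of
    doxorubicin-loaded electrospun nanofibers. Provides a calibrated synthetic
    generator for literature-mined formulation tables, an invertible
    preprocessing chain (per-column Box-Cox, SoftImpute matrix completion,
    min-max scaling), Spearman rank feature importance, per-label epsilon
    support-vector regression surrogates with radial-basis kernels, and
    particle-swarm inverse optimization that proposes fabrication parameters
    minimizing fiber diameter and maximizing encapsulation efficiency, drug
    release and anticancer activity, together with per-feature optimal ranges.
License: MIT
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
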