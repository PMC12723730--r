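Package: rdcsvd
Title: Multi-Tensor SVD Fitting of Residual Dipolar Couplings for
    Protein Domain Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits residual dipolar couplings (RDCs) to protein coordinates
    by singular value decomposition of the Saupe alignment tensor, for one
    conformer or for a population-weighted two-conformer equilibrium.
    Provides jackknifed quality factors, invariant-domain identification
    across crystal structures, bond-vector orientation averaging,
    alignment-tensor comparison and co-alignment, a two-state rotation
    grid search with a tensor-magnitude degeneracy guard, F-test/AIC model
    selection, closure/twist/bend decomposition of interdomain pose, and a
    noise-sensitivity simulator with Gaussian coupling noise and
    cone-distributed bond-vector noise.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
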