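Package: lols
Title: Low-Energy Latent-Space Conformer Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Active-learning conformer search for flexible molecules in
    torsion space.  An energy-weighted variational auto-encoder is trained
    on dihedral-angle data, new candidate conformations are drawn from its
    two-dimensional latent space by rectangle random sampling, and a
    Gaussian-process surrogate with a standard periodic kernel models the
    low-energy potential energy surface.  Local minima are extracted from
    the surrogate by conjugate-gradient descent, deduplicated, refined on
    the true energy backend, and ranked.  A synthetic periodic multi-well
    energy surface with brute-force enumerable minima serves as a
    self-contained test backend in place of quantum-chemistry engines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
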