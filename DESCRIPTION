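Package: optimshift
Title: Polygenic Versus Large-Effect Adaptation After a Shift in Trait Optimum
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Forward population-genetic models of a quantitative trait under
    Gaussian stabilizing selection responding to a sudden shift in the optimal
    trait value. Provides the allele-frequency distribution at
    mutation-selection-drift balance (diffusion sojourn-time quadrature and a
    Wright-Fisher burn-in engine), a stochastic hybrid engine coupling tracked
    large-effect alleles to a deterministic infinitesimal ('Fisherian')
    background that follows Lande's approximation, a fully polygenic engine, an
    analytic layer (Lande decay, establishment probabilities from a
    time-inhomogeneous branching process, the reach-one-half fixation
    approximation, regime classification, expected numbers of fixations), and
    replicate and grid-scan orchestration with Gaussian smoothing for mapping
    when adaptation proceeds through few large-effect fixations versus a
    polygenic response.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
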