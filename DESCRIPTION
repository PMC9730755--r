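Package: bundlekin
Title: Shape, Force and Motor Statistics of Kinesin-Driven Microtubule Bundles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of actively bending microtubule bundles
    driven by kinesin motor clusters. Bundle centerlines are represented as
    piecewise-clothoid (Euler spiral) splines fitted to traced contours by
    nonlinear least squares; tangent-tangent and curvature-curvature
    correlation functions with half-decay characteristic lengths summarize
    shape disorder; motor-generated shear force densities are reconstructed
    from the curvature derivative of the fitted splines; flexural rigidity is
    estimated from thermal shape fluctuations by cosine-mode equipartition.
    Motor-cluster trajectories are reduced to unidirectional run segments
    with reversal classification, and a two-rate Markov detachment/reversal
    model provides closed-form run-length distributions, rate estimation from
    observables, and derived reversal length scales. Seeded generators
    produce synthetic contours, thermally fluctuating filaments and motor
    track populations for end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
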