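Package: fizzdiff
Title: Diffusion of CO2 and Ethanol in Carbonated Water-Ethanol Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-simulation analysis of translational diffusion in carbonated
    water-ethanol mixtures, the model system for sparkling beverages. Computes
    mixture compositions from the alcoholic degree, estimates diffusion
    coefficients from mean-squared displacements of periodic-box trajectories
    with the Yeh-Hummer finite-size correction, derives experimental
    diffusivities from viscometry via the Stokes-Einstein relation, evaluates
    structural hydrodynamic radii (rms atomic distance and radius of gyration),
    counts hydrogen bonds with the geometric Chandler criterion, and evaluates
    the diffusion-limited bubble growth law. A Brownian-dynamics generator
    produces periodic-box trajectories with known ground-truth diffusion
    coefficients for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
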