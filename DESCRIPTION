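Package: optocoop
Title: Reaction-Diffusion Modelling of Light-Patterned Cooperation in Yeast
Version: 0.1.0
Authors@R:
    person("Plateforme", "Levure", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the growth of optogenetically controlled yeast lawns on
    sucrose gels, where illuminated cells produce periplasmic invertase
    (cooperators) and dark cells consume the released hexoses (cheaters).
    Implements the coupled reaction-diffusion model (Michaelis-Menten
    hydrolysis and uptake, Monod growth, sugar diffusion), illumination
    pattern generators, a method-of-lines solver with a well-mixed ODE
    oracle, the downstream readouts (growth curves, density profiles,
    cooperator benefit, spatial-bandpass cut-off wavelengths), and a
    synthetic plate-scanner observation model so the full analysis pipeline
    runs without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    optparse,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
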