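Package: tensiokin
Title: Adsorption Kinetics of Proteins at the Air-Water Interface
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the dynamic surface tension of protein solutions measured
    by hanging-drop tensiometry. Couples diffusion-limited transport inside a
    spherical drop to a surface-pressure-dependent free-energy barrier for
    adsorption, with an optional isodesmic cluster extension, an empirical
    surface pressure-surface excess equation of state, experiment protocols
    (bulk exchange, area steps), trace feature extraction (induction time,
    semistable surface tension), parameter fitting, and synthetic data
    generation for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
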