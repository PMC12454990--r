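Package: coldtherm
Title: Segmented Human Thermoregulation Modelling for Cold Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lumped-parameter simulator of human thermal physiology in still,
    cold air (0-14 degrees Celsius). The body is divided into 12 anatomical
    segments, each a stack of core, equivalent (muscle+fat), skin and optional
    clothing layers, coupled to a central blood pool. A passive system computes
    metabolic, conductive, convective-blood and respiratory heat flows; an
    active hypothalamic controller drives vasodilation, vasoconstriction and
    shivering from warm/cold receptor signals. Clothing is a pure thermal
    resistance; the environment couples through a calibrated still-air natural
    convection correlation. Includes steady-state and transient integration,
    ambient-temperature sweeps, thermal-resistance decomposition, equivalent
    layer heat-source calibration, synthetic button-logger skin-temperature
    generation and validation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
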