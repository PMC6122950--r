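Package: ejectkin
Title: Population Kinetics of Phage DNA Ejection from Calorimetric and
    Scattering Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the population dynamics of bacteriophage
    lambda DNA ejection triggered by the LamB receptor. Deconvolves
    isothermal titration calorimetry (ITC) heat-flow curves into one or two
    exponentially modified Gaussian (EMG) components to separate
    synchronized (fast) from desynchronized (slow) ejection populations;
    detects the intracapsid solid-to-fluid DNA transition temperature as a
    slope-inversion breakpoint in ejection enthalpy versus temperature;
    reduces time-resolved small-angle X-ray scattering (SAXS) frames to DNA
    diffraction peak areas and extracts Arrhenius activation energies from
    their decay rates; and normalizes light-scattering decays for
    cross-method comparison. A stochastic per-virion simulator renders
    ground-truthed synthetic ITC, light-scattering and SAXS observables with
    realistic instrument response, so every analysis stage is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
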