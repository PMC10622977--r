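Package: metabofract
Title: Multifractal Analysis of Metabolic Rate Time Series
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the complexity of oxygen-consumption time
    series from flow-through respirometry. Converts raw respirometry
    channels to VO2, extracts basal metabolic rate from steady-state
    windows, and forms log-ratio increment series; estimates generalized
    Hurst exponents, Renyi exponents and Legendre singularity spectra by
    multifractal detrended fluctuation analysis (MF-DFA); attributes
    observed multifractality to long-range correlations or heavy-tailed
    distributions via shuffling and amplitude-adjusted Fourier transform
    (AAFT) surrogates; computes recognition-index behavioral statistics
    and two-group comparisons; and integrates behavioral and physiological
    variables through Manhattan dissimilarities, principal coordinates
    analysis and PERMANOVA. Seeded synthetic-data generators (binomial
    multiplicative cascades with closed-form theory, fractional Gaussian
    noise, respirometry-like traces, two-group behavioral tables) support
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
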