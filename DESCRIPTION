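Package: paleodendro
Title: Dendrochronology and Paleosol Proxies for Deep-Time Paleoclimate
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for inferring paleoclimate from fossil tree rings and
    paleosol major-element chemistry. Implements statistical cross-dating of
    ring-width series (Baillie-Pilcher and Hollstein t-statistics, percent
    parallel covariation), smoothing-spline detrending to a ring-width index
    with subsample signal strength diagnostics, continuous wavelet transforms
    (Morlet and second-derivative-of-Gaussian) with red-noise significance and
    cone of influence, cross-wavelet power and wavelet coherence, a
    growth-suppression coincidence statistic linking significant wavelet
    coefficients to suppressed or enhanced growth years, and a paleosol
    weathering-index proxy chain (CIA, CIA-K, paleo-precipitation, land
    surface temperature, humidity provinces). A synthetic forest and paleosol
    generator provides statistically realistic inputs for testing every stage.
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
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
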