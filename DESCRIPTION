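Package: alphathal
Title: Biophysical Thalamic Network Model of the Occipital Alpha Rhythm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based (Hodgkin-Huxley) simulation of a scaled-down
    thalamic network that generates the ~10 Hz occipital alpha rhythm.
    High-threshold bursting thalamocortical (HTC) pacemaker cells, relay (TC)
    cells and reticular (RE) cells are coupled through kinetic AMPA, GABA-A and
    GABA-B synapses and gap junctions, and driven by Gaussian white noise and
    Poisson shot noise. The package quantifies rhythm frequency and coherence
    via the spectral entropy of the simulated local field potential, and
    provides seeded parameter-sweep experiments probing HCN (h-current)
    expression, cholinergic tone (potassium-leak modulation) and T-type calcium
    conductance, including the limited cholinergic rescue of a slowed alpha.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stats,
    generics,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
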