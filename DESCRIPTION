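Package: noisewalk
Title: Stochastic Noise Mapping and Occupational Exposure Simulation by
    Random Walk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates workplace noise by combining hemispherical sound
    propagation from machinery with a Pearson random walk for moving
    machines and workers. Predicts strategic noise maps (per-node LAeq
    grids with contour export), personal noise exposure (dose percentage
    and time-weighted average level), exceedance indices (L10/L50/L90),
    noise risk zoning with area percentages, and permissible-limit
    checks. Machine duty cycles (off/idle/full power) are sampled
    stochastically per simulation step, and barrier screening and facade
    reflection corrections follow the BS 5228-1 working approximation.
    Scenarios are described in plain-text configuration files and every
    run is reproducible from a single seed.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
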