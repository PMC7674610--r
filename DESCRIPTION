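Package: seedthresholds
Title: Thermal-Time and Hydrotime Threshold Analysis of Seed Germination
    and Seedling Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates ecophysiological threshold parameters of seed
    germination and normal-seedling development from dish-level scoring
    time courses: Boltzmann sigmoid fits of cumulative germination give
    t50 and rates, linear rate models give base temperatures (Tb) with
    thermal times (degree-hours) and base water potentials (Psi_b) with
    hydrotimes (MPa-hours), and concave quadratic fits give optimum
    temperatures. Includes a PEG-8000 osmoticum calculator (Michel
    polynomial), a ties-adjusted Spearman correlation matrix with exact
    small-sample p-values, a significance-filtered trait network with
    Girvan-Newman community detection, and population-threshold
    simulators so the whole chain is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
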