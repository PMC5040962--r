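Package: abysshill
Title: Terrain, Phytodetritus Cover and Megafauna Biomass Analysis for Abyssal Photographic Surveys
Version: 0.1.0
Authors@R: person("PAP", "Analyst", email = "analyst@example.org", role = c("aut", "cre"))
Description: Tools to link modest abyssal-hill topography to seafloor
    phytodetritus (particulate organic matter, POM) cover and invertebrate
    megafauna biomass. Provides bathymetric terrain derivatives (slope,
    rugosity, profile curvature) and annulus bathymetric position index (BPI)
    with primary and secondary terrain classification; colour segmentation of
    seabed photographs into light and dark POM classes with percent-cover
    estimation; allometric tile-level biomass estimation by feeding type;
    grid-cell aggregation with minimum-count filters and natural 12.5 m depth
    banding; a heteroscedastic statistics suite (Welch ANOVA, Games-Howell,
    Cohen's d, Brown-Forsythe Levene, simple and partial Spearman rank
    correlation, Mood's median test, Wilcoxon signed-rank median confidence
    intervals, empirical variograms); depth-only null models for POC flux and
    benthic biomass; and a seeded synthetic survey generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
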