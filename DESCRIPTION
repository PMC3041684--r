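Package: biomeshift
Title: Climate-Niche Summaries and Ancestral Biome Reconstruction on
    Time-Calibrated Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for eco-phylogenetic analysis of biome shifts in plant
    clades: per-collection climate-niche statistics (annual precipitation
    and Walter/Gaussen arid-month counts) from monthly climate vectors,
    pairwise Mann-Whitney U tests of niche differences within clades,
    maximum-likelihood ancestral-state reconstruction of habitat categories
    under the Markov k-state one-parameter (Mk1) model on a dated tree, and
    a likelihood-ratio (G) test of whether observed biome shifts on
    well-supported branches are fewer than expected under random assignment
    of habitats.  Includes a synthetic-data generator (Yule chronograms,
    Mk-evolved tip states, biome-conditioned occurrence climates) and a
    single-command pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape (>= 5.0),
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    optparse,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
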