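Package: cuhte
Title: Interpretable Success Prediction for Cu-Catalyzed C-N Coupling Screens
Version: 0.1.0
Authors@R: person("HTE", "Modeling Team", email = "hte@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for designing and modeling high-throughput
    Ullmann C-N coupling experiments. Provides training-set curation (property
    filtering, chemical-space embedding, Ward clustering, cross-cluster product
    pairing, control-experiment filtering), single-node decision-stump ligand
    classification with active-learning reselection, a three-node interpretable
    decision-tree yield classifier with fixed published thresholds
    (Cu-ligand distance 2.07 Angstrom, amine nitrogen NBO charge -0.803 au,
    bromide buried volume 33.5 percent), information-entropy prediction
    confidence with a radial-basis-function interpolated confidence map, a
    two-nearest-neighbor ligand recommender, and a seeded synthetic-data
    generator emulating the statistical structure of staged HTE campaigns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
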