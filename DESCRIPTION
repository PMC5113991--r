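Package: paraperm
Title: Paracellular Na+/Cl- Permeability and Junction Morphometry for
    Epithelial Monolayers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts transepithelial resistance (TER) and dilution-potential
    measurements into paracellular Na+ and Cl- permeabilities using the
    Goldman-Hodgkin-Katz dilution-potential equation and the Kimizuka-Koketsu
    conductance decomposition, with blank-filter correction, osmotic-gradient
    condition presets, and time-course summaries. Also quantifies the
    tortuosity ("zigzag index") of epithelial cell-cell contacts from traced
    junction geometry or labeled segmentation masks, and ships a seeded
    synthetic-data generator (relaxing-selectivity monolayer model, Voronoi
    epithelial meshes with tunable edge jaggedness) so the whole pipeline can
    be exercised and validated without wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
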