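Package: cwhto
Title: Virtual Closed-Wedge High Tibial Osteotomy Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Virtual surgical planning pipeline for lateral closed-wedge high
    tibial osteotomy (CWHTO) on three-dimensional proximal-tibia models.
    Constructs osteotomy planes for four techniques (conventional, oblique,
    hybrid 3:1 and hybrid 2:1 hinge positions) at arbitrary coronal correction
    angles, executes the cuts on watertight triangle meshes, and measures
    osteotomy surface areas, resected wedge volumes, medial gap volumes and
    the non-overlapping (overhang or gap) areas that remain after closure of
    the osteotomy gap. Includes a parametric proximal-tibia phantom generator
    with cohort-level anatomical variation, batch simulation over knees x
    techniques x correction angles, summary tables with percent ratios, and
    nonparametric two-sample group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    polyclip,
    stats,
    utils,
    tibble,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
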