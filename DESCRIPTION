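Package: beetmorph
Title: Automated Histologic Phenotyping of Beet Storage-Root Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated evaluation of cell characteristics and tissue arrangement
    in transverse-section micrographs of Beta vulgaris storage roots. Segments
    cells by distance-transform watershed, discriminates real cells from
    intercellular spaces and artifacts by neighborhood outlier analysis and
    iterative size-ordered k-means clustering, detects cambium rings from the
    smoothed cell-diameter profile along the periderm-to-center axis, assigns
    cells to vascular tissue or storage parenchyma, and emits per-image and
    per-genotype morphometric summary tables, kernel density estimates of cell
    size, and an Earth Mover's Distance similarity dendrogram. Includes a
    seeded synthetic tissue generator with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    ape,
    graphics,
    grDevices,
    stats,
    tools,
    utils,
    yaml,
    zoo
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
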