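Package: octarp
Title: Quantification of Retinitis Pigmentosa Progression from OCT Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies longitudinal retinal vascular change in retinitis
    pigmentosa from en-face OCT angiography: iterative-intermeans (IsoData)
    binarization of the capillary plexus slabs, foveal avascular zone (FAZ)
    delineation from manual outlines or an automated flood-fill surrogate,
    perfusion density with FAZ exclusion, choriocapillaris mean gray value,
    ellipsoid-zone line width from foveal reflectivity profiles, and the
    per-eye change-over-time statistics battery (one-sample and paired
    t-tests, Pearson correlation grids, two-grader averaging). Includes a
    seeded synthetic angiogram and cohort generator with known ground truth
    so every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
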