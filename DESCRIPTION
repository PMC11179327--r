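Package: cbtmorph
Title: Cortical Bone Thickness Morphometry of the Tibia from CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sub-voxel cortical bone thickness (CBT) estimation from CT
    volumes by model-based fitting of blurred density-step intensity profiles
    along surface normals, together with the anatomical tibial coordinate
    system, standardized 24-region diaphyseal CBT aggregation, femorotibial
    angle (FTA) and medial tibial plateau coronal inclination morphometry,
    and the accompanying statistics layer (normality-gated tests, intraclass
    correlation, and exact-power sample-size calculation for correlations).
    A synthetic phantom and cohort generator with known ground truth drives
    the full pipeline so that no patient data are required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    grDevices,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
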