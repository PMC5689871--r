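Package: fluqa
Title: 3D Primary Fluence Reconstruction for Radiotherapy Delivery QA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs 3D volumetric primary beam fluence for IMRT/VMAT
    treatment delivery verification by forward-projecting MU-weighted MLC
    apertures from DICOM-RT plans and fixed-interval delivery log records.
    Delivered and planned fluence volumes are compared with a 3% intensity
    difference test and a 3%/3 mm 3D gamma analysis; an error-injection
    framework simulates gantry, MU, jaw, collimator and MLC delivery errors
    and sweeps their magnitudes to characterise QA sensitivity. Includes a
    synthetic plan/log generator so the full pipeline runs without clinical
    data, plus minimal DICOM RT Plan and NRRD volume I/O.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, graphics, grDevices, tools, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
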