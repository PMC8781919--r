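Package: fdkrecon
Title: Cone-Beam CT Reconstruction by Feldkamp-Davis-Kress Filtered Backprojection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete processing chain for circular cone-beam computed
    tomography: flat-field/dark-field normalization with three fluence
    correction options, polynomial beam-hardening linearization, ring-artifact
    reduction by defect-pixel median filtering and by detector-line-ratio
    sensitivity correction, cosine weighting and discrete spatial-domain
    Ram-Lak/Shepp-Logan ramp filtering, voxel-driven FDK backprojection with
    memory-budgeted chunking for arbitrarily large data, and automatic
    geometry calibration (rotation-axis offset by an autofocus sharpness
    criterion, axis tilt by linear least squares).  An analytic ellipsoid
    phantom simulator with artifact injection provides ground truth for
    validation, and a command-line interface drives the pipeline headless.
License: MIT
Encoding: UTF-8
Imports:
    tiff,
    stats,
    graphics,
    grDevices,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
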