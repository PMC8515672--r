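Package: jawtrack
Title: Six-Degree-of-Freedom Jaw Kinematics, Dynamic Occlusion and EMG
    Synchronization for Small-Animal Mastication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs three-dimensional mandibular movement relative to
    the maxilla from marker-based motion capture and micro-CT derived surface
    anatomy. Provides least-squares rigid registration of marker clouds
    (Kabsch/Procrustes), per-frame six-degree-of-freedom pose estimation,
    landmark trajectory reconstruction in a maxilla-fixed anatomical frame,
    per-frame occlusal clearance and contact-interval detection between
    dentition meshes, masticatory-cycle phase segmentation (opening, closing,
    occlusal), EMG envelope and burst-onset analysis synchronized to capture
    frames, and the step-resolution / calibration-grid protocols used to
    evaluate such tracking systems. A synthetic-data generator produces
    ground-truth chewing motion, noisy marker captures, toy cusp-and-fossa
    dentition meshes and phase-locked EMG so the full pipeline is testable
    without capture hardware.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
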