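Package: basketmap
Title: Virtual Basket-Catheter Phase Mapping of Simulated Atrial Rotors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation study of rotor detection by multi-electrode
    basket catheters. Implements the Courtemanche-Ramirez-Nattel human atrial
    action-potential model with nine regional conductance variants and
    chronic-AF remodeling, a monodomain reaction-diffusion solver on sheets
    and cylindrical surfaces, unipolar electrogram forward computation in an
    infinite volume conductor, band-pass/Hilbert instantaneous-phase mapping,
    topological-charge phase-singularity detection and tracking, a parametric
    spherical basket catheter with periodic 2-D interpolated projections, and
    classification of detected singularities into true rotors, far-field
    imaginary singularities (IMPS) and interpolation artifacts (FIPS).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
NeedsCompilation: yes
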