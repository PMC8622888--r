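Package: sinterfit
Title: Lemniscate-of-Booth Contour Fitting and Viscous Sintering Kinetics
    for Coalescing Thermoplastic Filaments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to monitor the hot-melt coalescence (viscous sintering) of
    two juxtaposed cylindrical thermoplastic filaments from backlit time-lapse
    image sequences. Each 8-bit frame is segmented, the silhouette contour is
    extracted by binary erosion and converted to centered polar coordinates,
    and a lemniscate of Booth r(phi) = a * sqrt(cos(phi)^2 + B^2 * sin(phi)^2)
    is fitted to the contour by derivative-free least squares. The per-frame
    shape parameter is mapped to Hopper's coalescence parameter m and the
    characteristic viscous sintering time t_vs is estimated by matching the
    measured dm^2/dt against the dimensionless master curve of Hopper's exact
    plane-flow solution. A forward simulator renders ground-truthed synthetic
    sequences so the whole pipeline can be validated closed-loop without any
    experimental data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    pracma,
    graphics,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
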