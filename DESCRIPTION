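Package: sarcopack
Title: Quantitative Sarcomere Architecture from Traced Myofilaments and
    Subtomogram Averaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of sarcomere architecture in
    cryo-electron tomograms of striated muscle. Provides synthetic generators
    for myofilament lattices, polarity-segmented sarcomeres and helical
    thin-filament density volumes; centerline resampling and zxz Euler pose
    initialisation; near-neighbor (d, theta) packing statistics with
    first-shell spacing estimation and local-frame packing heatmaps;
    desk-scale subtomogram extraction, constrained alignment and averaging
    with Fourier shell correlation; two-reference statistical assignment of
    actin filament polarity; and polarity-derived sarcomere metrics (Z-disk
    and M-line location, thin-filament overlap, helical rise and twist,
    tropomyosin azimuthal shift).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
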