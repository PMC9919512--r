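Package: ippg
Title: Imaging Photoplethysmography and Pulse Rate Variability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Contactless cardiovascular assessment from face video.
    Extracts blood-volume-pulse signals from per-frame RGB traces by eight
    alternative algorithms (green-red difference, adaptive green-red
    difference, principal and independent component analysis, Laplacian
    eigenmaps, stochastic proximity embedding, and the chrominance-based
    CHROM and plane-orthogonal-to-skin POS projections), conditions them
    with smoothness-priors detrending, moving-average and band-pass
    filtering, continuous-wavelet filtering and empirical mode
    decomposition, derives pulse rate and pulse rate variability features
    in the time, frequency and nonlinear (Poincare) domains, and
    quantifies agreement against a contact photoplethysmography reference
    with Spearman correlation, normalized root mean square error and
    Bland-Altman limits of agreement. A seeded synthetic-data generator
    produces ground-truthed interbeat series, pulse waveforms,
    skin-coupled RGB traces and rendered face videos for end-to-end
    validation without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    Matrix,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
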