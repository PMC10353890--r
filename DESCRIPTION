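Package: flycourt
Title: Analysis of Light-Induced Courtship Behaviour in Multi-Fly Arenas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for quantifying social and courtship behaviour of
    groups of Drosophila in circular arenas under programmable light
    protocols. Provides an agent-based simulator of multi-fly locomotion
    with light-dependent chasing and chaining, frame rendering and
    courtship-song synthesis; centroid detection and identity linking for
    arena video; proximity-based interactograms with chase and chain event
    detection; per-fly locomotor kinematics; interval-based behaviour
    scoring across light epochs with paired and multi-group statistics,
    dose-response summaries and spectral normalization; and pulse/sine
    courtship-song segmentation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    grDevices,
    generics,
    signal,
    pracma,
    withr,
    EBImage,
    jsonlite,
    readr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png
Config/testthat/edition: 3
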