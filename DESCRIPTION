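Package: netcurv
Title: Discrete Ricci Curvature and Anomaly Detection for Weighted Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes an order-d, 2-complex Forman-Ricci curvature for
    weighted undirected networks, with faces built by gluing triangles
    along shared edges, and uses per-edge curvature differences between
    two snapshots of a network (for example control and disease brain
    connectomes) to detect local anomalies.  Includes an exact
    Ollivier-Ricci comparator based on optimal transport, a
    degree-preserving edge-swap null model with a pinned node pair for
    z-score significance testing, threshold sparsification of
    connectivity matrices, and generators for synthetic thresholded
    correlation networks with planted perturbations.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    boot,
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
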