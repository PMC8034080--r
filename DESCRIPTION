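Package: rootct
Title: Segmentation and Quantification of Plant Root Systems in X-Ray CT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Shape-based segmentation of plant roots from 3D X-ray computed
    tomography images of soil columns. Implements a full processing chain:
    grayscale conditioning (percentile stretch, stack stitching with
    attenuation correction, non-local-means denoising, unsharp masking),
    interpolated pot-wall masking with histogram peak analysis, absolute
    difference transform background removal, multi-scale Hessian tubeness
    filtering with automatically calibrated hysteresis thresholds, shape-based
    false-negative recovery via ellipsoid vesselness scoring, and
    quantification of root length density and diameter distributions from
    skeletons and local thickness maps. Includes a synthetic phantom generator
    for roots in granular soil with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    FNN,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
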