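Package: colloidspot
Title: Detection of Colloidal Particles in Porous-Media Micromodel Image
    Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting micrometre-scale colloidal particles in
    grayscale microscopy image sequences of porous-media micromodels.
    Implements eight classical detectors in four families (k-means and Otsu
    intensity segmentation; two/three-frame differencing, frame differencing
    plus background subtraction, and multi-frame differencing; Laplacian and
    Difference-of-Gaussians spot filters; grayscale dilation and top-hat
    morphology), an object-level majority-vote ensemble of the three best
    detectors, ground-truth matching with Precision, Recall, F-measure and
    Target-to-Clutter Ratio, Friedman rank benchmarking with Holm-adjusted
    pairwise post hoc comparisons, and a synthetic micromodel scene
    generator that renders three-level (grain, pore, colloid) image
    sequences with per-frame ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    png,
    stats,
    tiff,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
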