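Package: harmonyseg
Title: Harmony-Search-Initialized Fuzzy C-Means Segmentation of Grayscale
    Biomedical Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments grayscale biomedical images (for example brain MRI
    slices) by intensity clustering.  Implements a harmony search optimizer
    whose harmony memory is constructed from the data via rough-set
    lower/upper approximations with k-nearest-neighbour refinement, together
    with adaptive pitch-adjusting-rate and bandwidth schedules.  The optimized
    cluster centers initialize fuzzy c-means clustering; partition coefficient
    and partition entropy validity indices score the resulting fuzzy
    partitions and support comparison against randomly initialized fuzzy
    c-means.  A seeded phantom generator with ground-truth label maps makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
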