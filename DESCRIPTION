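Package: nbquant
Title: Quantification of Coilin-Positive Nuclear Bodies in 3D Confocal Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for quantifying coilin-positive nuclear
    bodies (Cajal bodies and related structures) in two-channel 3D confocal
    image stacks. The pipeline crops individual nuclei from the DAPI channel,
    segments punctate nuclear bodies in the protein channel by 3D Gaussian
    smoothing, prominence-based 3D maxima detection and seeded geodesic
    threshold segmentation, and extracts per-body and per-nucleus
    morphometric parameters (bounding-box diameter, maximum gray value).
    A statistical battery for ordered age groups is included: exact r x c
    (Freeman-Halton) contingency testing with pairwise Bonferroni follow-up,
    pairwise Mann-Whitney tests, the Jonckheere-Terpstra ordered-trend test
    and Kendall rank correlation, together with a synthetic two-channel
    fluorescence-stack generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
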