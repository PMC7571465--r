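Package: rilmap
Title: Bin-Marker Genotyping, Linkage Maps and ICIM QTL Scanning for RIL Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for high-density genetic mapping in recombinant inbred line
    (RIL) populations genotyped by low-coverage resequencing. Converts parental
    and progeny SNP calls into bin markers with a 15-SNP sliding-window
    genotyper, builds linkage maps by nearest-neighbour/two-opt ordering with
    SARF rippling and Kosambi distances, computes leaf-shape phenotype indices
    (apex count, lobed-area ratio R, length ratio Q), and maps QTL by inclusive
    composite interval mapping (ICIM) with permutation-based LOD thresholds.
    Includes a single-seed-descent RIL simulator with a read-depth observation
    model and parametric lobed-leaf outlines, providing ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    vcfR,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
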