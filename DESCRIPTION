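Package: radialchrom
Title: Radial Chromatin Distribution Profiling in Polytene Nuclei
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the radial distribution of DAPI-stained chromatin in
    polytene nuclei from confocal images. Computes concentric-ring integrated
    intensity profiles on the equatorial focal plane, converts them to relative
    radial coordinates, bins them into twenty 5% intervals, compares two groups
    of nuclei per interval with the Mann-Whitney U test, and summarises the
    change over radial thirds with an interval-change statistic. Includes a
    synthetic-nucleus image generator with known ground truth for validating
    every stage, nucleus segmentation and equatorial-plane selection for
    z-stacks, and sequence-level verification arithmetic for frameshift
    alleles (substitution splicing, translation, novel-peptide length,
    antibody-epitope integrity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Biostrings,
    tiff,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
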