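Package: shp2dms
Title: Two-Construct Deep Mutational Scanning Analysis of SHP2 Auto-Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing paired deep mutational scans of the tyrosine
    phosphatase SHP2 performed on the full-length protein and on its isolated
    catalytic (PTP) domain. Includes a mechanistic simulator of the yeast
    growth-rescue selection assay with a planted ground-truth landscape in
    which full-length activity is the product of intrinsic catalytic activity
    and an auto-inhibition release factor; tile-based (MITE-style) library
    design; wild-type-normalized enrichment scoring with replicate QC;
    Gaussian and two-component Gaussian-mixture fitting of score
    distributions with wild-type-centered significance thresholds; funnel
    classification of PTP-domain variants into mechanistic regions I-IV;
    clinical-annotation group summaries; single-nucleotide accessibility of
    amino-acid substitutions; and geometric order parameters (distances,
    backbone psi and side-chain chi1 dihedrals) computed from PDB coordinate
    files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
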