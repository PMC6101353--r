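Package: pepmap
Title: Quantitative and Modification-Aware Mapping of Peptides to Genome Coordinates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps peptides identified by tandem mass spectrometry onto
    reference genome coordinates using standard gene annotation (GTF) and
    protein-coding transcript translation sequences (FASTA). Supports
    post-translational modifications, per-sample quantitation, and mapping of
    variant peptides with up to two amino-acid mismatches via a k-mer index
    with pigeonhole candidate generation. Emits genome-browser-ready output:
    BED12 with a three-tier uniqueness colour code, PTM BED pairs with
    thick-block modification highlighting, GTF, GCT expression matrices split
    at splice junctions, and UCSC track-hub scaffolding. Includes a synthetic
    fixture generator with planted ground truth so the complete workflow is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
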