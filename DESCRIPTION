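Package: siroclass
Title: Signature-Based Classification of Siroheme Sulfite Reductase-Like
    Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotates and classifies dissimilatory sulfite
    reductase-like proteins (Dsr-LP) from protein FASTA input by locating
    conserved sequence signatures: the coupled siroheme-[Fe4-S4] cysteine
    anchors, the peripheral and additional [Fe4-S4] cluster motifs, and
    four sulfite-binding Arg/Lys positions. Assigns group (I/II/III) and
    subgroup (a-d) labels, detects chimeric F420H2-dependent sulfite
    reductase (Fsr) architectures arising from gene fusion, and classifies
    FrhB-core domain architectures (FrhB-like, FpoF-family, FdhB-like).
    Includes affine-gap global alignment with anchor-column mapping,
    center-star multiple alignment with gap-fraction column trimming, a
    neighbor-joining tree stage with bootstrap support and monophyly
    testing, and a synthetic sequence generator that plants or ablates
    each signature with tunable noise for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ape,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
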