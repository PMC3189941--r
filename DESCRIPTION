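Package: orthodiv
Title: Ortholog Divergence and Selection Scans for Closely Related Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-transcriptomics toolkit for pairs of closely related
    species. Identifies orthologous transcript pairs by reciprocal best hit
    with paralog removal via unambiguous shared protein hits, delineates
    CDS and UTR regions guided by reference proteins, computes
    context-stratified sequence divergence (CpG/non-CpG, nondegenerate and
    fourfold-degenerate sites, transition/transversion ratios), and
    estimates Ka/Ks per ortholog pair with Nei-Gojobori (1986) counting and
    a Yang-Nielsen (2000)-style approximate method. Includes a synthetic
    two-species transcriptome generator with a complete ground-truth channel
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
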