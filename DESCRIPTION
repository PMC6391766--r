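Package: mybevol
Title: Molecular Evolution and Expression Analysis of Duplicated Plant
    Myb Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "dev@example.org", role = c("aut", "cre"))
Description: Tools for comparative-evolution analysis of small duplicated
    transcription-factor gene families in cereals: pairwise synonymous and
    nonsynonymous substitution rates (Ks, Ka) by the (modified) Nei-Gojobori
    counting method with Jukes-Cantor correction, molecular-clock calibration
    and duplication dating, Neighbor-Joining phylogenies with bootstrap
    support, promoter cis-element scanning with IUPAC motifs and indel calling
    from affine-gap global alignments, and relative expression analysis of
    qPCR Ct tables (2^-ddCt) with ANOVA letter groups and exact Mann-Whitney
    U comparisons. A synthetic-data module generates clock-evolved coding
    sequence families, motif- and indel-bearing promoters and replicated Ct
    tables with ground-truth manifests for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
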