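Package: nucqc
Title: Quality Control, Reference Selection and Feature Quantification for
    MNase-Seq Nucleosome Organization Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for working with MNase-seq derived nucleosome organization
    maps. Builds nucleosome occupancy and array-regularity signal tracks from
    sequenced fragments, computes a six-metric sample quality-control panel
    (sequencing coverage, AA/TT/AT dinucleotide periodicity, nucleosomal DNA
    length, nucleosome depletion at transcription start sites, nucleosome
    fuzziness downstream of transcription start sites, and nucleosome array
    enrichment at DNase hypersensitive sites), ranks and pools samples within
    a cell type to select a referenced nucleosome landscape, quantifies
    per-locus nucleosome features (depletion level, occupancy, array scores,
    +1/-1 nucleosome position, linker length statistics and nucleosome
    counts), and evaluates whether nucleosome organization features improve
    motif-based transcription factor binding-site prediction with logistic
    regression and cross-validated ROC/AUC. A synthetic data generator
    produces genomes, fragment sets, annotations and binding datasets with
    known ground truth for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    rtracklayer,
    glmnet,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
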