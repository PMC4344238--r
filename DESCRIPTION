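Package: trninfer
Title: Integrated Inference of Bacterial Transcriptional Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Reconstructs genome-scale bacterial transcriptional regulatory
    networks (TRNs) by integrating comparative genomics with gene expression
    data and intrinsic properties of transcription factors. Implements
    phylogenetic footprinting of upstream intergenic regions across related
    genomes (ZOOPS de novo motif discovery, exact scan p-values, motif
    clustering), expression-based bicluster refinement of motif-defined gene
    sets, a four-criterion transcription-factor-to-cluster linker with
    permutation p-values (expression correlation, genomic proximity,
    DNA-binding-domain motif similarity and phylogenetic correlation), an
    expression-only consensus network (CLR-style mutual information and
    tree-ensemble scorers), precedence-based network merging, precision-recall
    evaluation utilities, and a fully self-contained synthetic data generator
    with known ground truth for benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    ranger,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
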