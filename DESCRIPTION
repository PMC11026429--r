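Package: ksphase
Title: Synonymous-Divergence Phasing and Dating of Allopolyploid Subgenomes
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for reconstructing the origin of allopolyploid plant
    genomes from synonymous substitution rates (Ks) and comparative
    karyotypes. Implements Nei-Gojobori (1986) codon-level Ks/Ka estimation
    with Jukes-Cantor correction, ortholog copy-number filtering, chromosome
    level Ks aggregation with exact two-cluster subgenome assignment,
    molecular dating via T = Ks/(2*mu), symbolic algebra over ancestral
    crucifer genomic-block karyotypes (whole-genome duplication, nested
    chromosome insertion, inversion), k-mer based genome-size estimation,
    and utilities for temporal classification of differentially expressed
    genes and leaf-shape dissection indices. Ships a synthetic allotetraploid
    data generator so every stage can be exercised and validated against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
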