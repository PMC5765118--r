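Package: plateletIR
Title: Intron Retention Quantification and Proteogenomic Junction-Peptide
    Analysis for Platelet Activation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies intron retention (IR) from stranded, gapped RNA-seq
    alignments, calls activation-induced intron removal with permutation
    statistics, builds a three-frame exon-exon junction peptide database
    from retained introns, maps identified peptides onto junction windows,
    and integrates intron removal with protein and junction-peptide
    accumulation across stimulation conditions. Includes a synthetic-data
    generator with known ground truth (toy genome, annotation, per-sample
    SAM alignments, protein and peptide tables) emulating a three-replicate
    resting versus agonist-stimulated platelet design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
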