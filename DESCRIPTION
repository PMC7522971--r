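Package: minkmap
Title: Recessive Variant Segregation and Coding-Consequence Analysis for
    Mink Coat-Colour Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for discovering recessive Mendelian coat-colour
    genes from multi-sample variant calls. Implements a case/control
    segregation filter that selects genes carrying homozygous or
    compound-heterozygous depth-passing variants in all affected animals
    and in no unaffected animal; a coding-consequence engine (HGVS c.
    parsing and formatting, strand-aware genomic-to-CDS projection with
    3'-shifting, frameshift translation with stop-codon scanning into the
    3'UTR, and VEP-style impact tiers); cis/trans phase inference from
    allele-specific amplicon observations; a synthetic-cohort generator
    with planted causal genes and a truth record; and Table-1 style
    genotype tabulation with a recessive-model concordance summary.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
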