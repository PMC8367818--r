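Package: taxmine
Title: Genome Mining and Molecular Evolution of the Paclitaxel Pathway
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale toolkit for the comparative-genomic and expression
    analyses used to dissect paclitaxel biosynthesis in a conifer genome:
    Nei-Gojobori (NG86) Ka/Ks estimation with Jukes-Cantor correction and
    4DTv transversion rates for whole-genome-duplication detection, Kimura
    two-parameter dating of LTR retrotransposon insertions (T = D/2mu),
    reciprocal-best-hit paralogue screens with c-score filtering, physical
    grouping of CYP450 genes on pseudochromosomes, jasmonate group-response
    scoring from RPKM profiles, a three-round subtraction screen with an
    anchor-gene Pearson coregulation network, p-distance neighbour-joining
    trees, and Michaelis-Menten kinetics for taxadiene synthase assays.
    A synthetic-data module generates gene layouts, codon pairs, LTR pairs
    and negative-binomial expression studies with known truth so the whole
    pipeline is testable without the original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    ape,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
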