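Package: metaPair
Title: Integrated Analysis of Paired Metagenome and Metatranscriptome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the joint analysis of paired shotgun metagenomic (DNA)
    and metatranscriptomic (RNA) sequencing of microbial communities. Provides
    lowest-common-ancestor taxonomic binning of reads from tabular protein
    alignment hits, best-hit orthologous-group (NOG) annotation, cumulative sum
    scaling and reads-per-million normalization, moderated-t differential
    abundance with Benjamini-Hochberg control, integration of DNA and RNA fold
    changes through an ordinary-least-squares prediction-interval outlier
    classification of transcriptionally responsive functions, pre-ranked gene
    set enrichment analysis with a rank-permutation null, PERMANOVA and
    hypergeometric enrichment statistics, genus-per-NOG contribution matrices,
    and a synthetic-community generator that plants known effects so every
    stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    BiocGenerics,
    limma,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
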