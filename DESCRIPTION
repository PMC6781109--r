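Package: gbmnoise
Title: Gene-Body Methylation, Single-Cell Expression Noise and Intron
    Retention in Arabidopsis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline linking gene-body methylation (gbM) to
    single-cell gene expression noise, expression consistency and intron
    retention in Arabidopsis thaliana root quiescent-centre cells.
    Classifies genes as gbM, unmethylated, ambiguous or highly methylated
    non-gbM from bisulfite-sequencing cytosine counts via binomial tail
    probabilities; quantifies per-gene stochastic expression (F*, the
    ratio of observed to trend-expected variance after polynomial
    decorrelation of log variance against log mean), transcriptional
    noise (coefficient of variation) and expression consistency from an
    FPKM matrix; counts reads mapping to introns of non-overlapping
    genes; and disentangles direct from covariate-mediated gbM effects
    with centred/scaled ANCOVA, all-subsets BIC model averaging,
    variance-inflation screening and principal-component regression.
    Includes a seeded synthetic-data generator with planted ground truth
    so every stage is exercisable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    data.table,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
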