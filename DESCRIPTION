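Package: hydroxyscan
Title: Promoter Tiling-Array Analysis of the Liver 5-Hydroxymethylome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for 5-hydroxymethylcytosine (5hmC) and
    5-methylcytosine (5mC) immunoprecipitation profiles measured on promoter
    tiling arrays, together with the surrounding assays used to interpret
    them: loess and scale normalization of probe-level log2(IP/input) scores,
    percentile-threshold probe-window peak calling, unique assignment of
    peaks to genic categories, TSS-centred sliding-window meta-profiles,
    region-count scoring of histone-mark ChIP-seq fragment libraries, CpG
    density classification of promoters, an information-theoretic tissue
    specificity score, glucosylation/restriction qPCR quantification of
    absolute 5hmC/5mC fractions, and differential analysis of drug-induced
    changes in all marks. A synthetic-data generator emulates the array
    geometry and plants known effects so that every stage of the pipeline is
    verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
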