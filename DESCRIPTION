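Package: tailfrac
Title: Transcriptome-Wide Poly(A)-Tail Length Analysis from Fractionated RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers transcriptome-wide changes in poly(A)-tail length from
    RNA-seq of mRNA pools fractionated by oligo(dT) capture stringency into
    short-tail and long-tail fractions. Provides a seeded synthetic-data
    generator with known ground truth (tail-length-dependent fraction
    allocation, spike-in controls, planted 3'-UTR motifs), count filtering and
    trimmed-mean-of-M-values (TMM) normalization, per-gene negative-binomial
    inference of the long/short fraction ratio and its genotype-dependent
    change, gene-set rank-sum enrichment against the transcriptome-wide
    background, 3'-UTR hexamer and base-composition association, and
    validation-assay arithmetic (spike-in abundance proxies, qPCR estimates,
    extension poly(A) test trace analysis, and segregation chi-square tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml,
    Biostrings
Suggests:
    edgeR,
    MASS,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
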