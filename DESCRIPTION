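Package: aneuscreen
Title: Pooled Barcode Fitness Screening of Gene Duplications in Aneuploid Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pooled barcode-sequencing (Bar-seq)
    competitive fitness screens of single-gene duplications in euploid and
    aneuploid yeast. Provides exact-match barcode counting from FASTQ,
    TMM-normalized log2 fold-change fitness scores with moderated-t
    significance calls, threshold rules for context-specific detrimental and
    beneficial gene sets with hypergeometric enrichment, cumulative-burden
    linear models of chromosome fitness costs and Ssd1 dependence, a
    multiplicative-null drug-by-aneuploidy interaction test, and a mechanistic
    simulator of pooled competitive growth with full ground truth for
    recovery and calibration testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    edgeR,
    Biostrings,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
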