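Package: aerlnc
Title: Ligand-Independent Estrogen-Receptor-Regulated lncRNA Catalog and
    Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds and characterizes catalogs of long non-coding RNAs
    regulated by unliganded (apo) estrogen receptor alpha in breast cancer
    cells.  Provides a minimal negative-binomial differential-expression
    test with cross-method consensus integration and lncRNA-specific
    biotype/length/blacklist filters; TSS-to-binding-site distance
    enrichment against biotype-matched resampling nulls; binned ChIP-seq
    signal matrices with promoter/enhancer calls from the
    H3K4me3/H3K4me1 ratio; cross-validated chi-squared attribute merit
    for luminal-signature selection with perceptron classification, Ward
    clustering and PCA; guilt-by-association Pearson co-expression
    screening; and bootstrap quantile-regression harmonization of
    two-run qRT-PCR delta-Ct series.  A synthetic-data module generates
    every input the pipeline consumes, with planted ground truth, so the
    whole workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nnet,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
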