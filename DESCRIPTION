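Package: ptmdiff
Title: Differential Abundance of Proteins and Histone Post-Translational
    Modifications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-group differential abundance analysis for mass-spectrometry
    intensity tables of whole proteomes and histone post-translational
    modifications (PTMs). Provides beta-value and logit (M-value) relative
    abundance transforms with offset regularization, an empirical-Bayes
    moderated t-test with variance shrinkage implemented from first
    principles, Benjamini-Hochberg false discovery rate control,
    writer/eraser/reader modifier-protein annotation, diagnostic and result
    plots (histogram, boxplot, PCA, MDS, volcano, clustered heatmaps,
    stacked beta bar charts), and seeded simulators of protein and PTM data
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ggplot2,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse,
    jsonlite
Config/testthat/edition: 3
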