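Package: epichrom
Title: Methylation Heterogeneity, DNMT Sequence Specificity, Nucleosome
    Fibers and Restraint-Based 3D Chromosome Models in Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for synthetic-methylome experiments in budding
    yeast expressing mammalian DNA methyltransferases. Implements a binomial
    mixture model with EM fitting and likelihood-ratio homogeneity tests for
    per-read CpG methylation counts, logistic-scale estimation of sequence
    context (6-mer) effects on CpG methylation, Gaussian deconvolution of
    MNase-seq coverage into nucleosome families with a coarse-grained
    Monte Carlo chromatin-fiber model, restraint-based 3D chromosome modeling
    from Hi-C contact matrices (iterative correction, power-law
    contact-to-distance conversion, flat-welled harmonic restraints, annealed
    sampling and greedy ensemble selection), structural metrics (radius of
    gyration, per-bead flexibility, relative telomere distances), anchored and
    gene-body signal profiles, and a synthetic-data module that generates all
    inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
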