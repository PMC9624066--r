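Package: neurofusion
Title: Cross-Modal Multivariate Decoding and Representational Similarity
    Fusion for EEG, ECoG and fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing visual object representations across
    electroencephalography (EEG), electrocorticography (ECoG) and
    functional magnetic resonance imaging (fMRI) at the level of
    population codes.  Implements time-resolved one-vs-rest category
    decoding with pseudo-trial averaging and multivariate noise
    normalization, identity-preserving cross-decoding (rotation and
    scale invariance), representational similarity analysis with
    1 - Spearman dissimilarities, cross-modal representational fusion,
    noise-ceiling signal-to-noise proxies, and nonparametric inference
    (Wilcoxon signed-rank timecourses, FDR control, onset/peak latency
    extraction, participant bootstrap, condition-label permutation
    tests).  A synthetic-data generator emulates a 125-condition object
    design (5 categories x 5 identities x 5 viewing conditions) with
    known ground-truth effect sizes, latencies and regional
    signal-to-noise, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
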