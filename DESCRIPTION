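Package: plimox
Title: Time-Resolved Luminescence Oximetry and Dendrogram Analysis of
    Lifetime Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for oxygen sensing with phosphorescent
    probes such as [Ru(Phen)3]2+: simulation and least-squares fitting of
    time-binned luminescence decays (mono-exponential, and bi-exponential
    with a fixed long-lived component), Stern-Volmer conversion of mean
    lifetimes to percent oxygen, distribution-asymmetry (rel_Md) and
    out-vs-in contrast (rel_OI) indicators, Ward.D2 hierarchical
    clustering of six-number lifetime summaries with cophenetic distances
    and Newick export, per-pixel lifetime-map analysis (histograms, ROI
    statistics, bimodal splits, oxygen maps), and a synthetic-data
    generator emulating per-condition lifetime distributions and
    two-population lifetime scenes so that every stage is testable
    without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
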