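Package: il2rameta
Title: Meta-Analysis of IL2RA Polymorphisms and Type 1 Diabetes Risk
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reproduces a genetic-association meta-analysis of five IL2RA
    single nucleotide polymorphisms (rs11594656, rs2104286, rs3118470,
    rs41295061, rs706778) with type 1 diabetes from study-level summary
    data. Provides allelic odds-ratio extraction from genotype counts
    (Woolf method) or reported confidence intervals, Hardy-Weinberg
    equilibrium screening, inverse-variance fixed-effect and
    DerSimonian-Laird random-effects pooling with Mantel-Haenszel support,
    Cochran's Q and I-squared heterogeneity metrics with a disjunctive
    model selector, leave-one-out influence and heterogeneity-targeted
    sensitivity analysis, Egger regression and Begg-Mazumdar
    rank-correlation publication-bias tests, Wacholder false-positive
    report probability grids, and a calibrated synthetic case-control
    study generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
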