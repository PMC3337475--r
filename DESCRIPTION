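Package: cermod
Title: Conserved Motif Scanning and Cis-Regulatory Module Detection for
    Nematode Promoters
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for position-weight-matrix (PWM) representation, log-odds
    scoring and both-strand promoter scanning with exact score-distribution
    cutoffs; consolidation of redundant motif matrices by the average log
    likelihood ratio (ALLR) similarity statistic; detection of cis-regulatory
    modules (CRMs) from clustered binding sites via per-position site-density
    Z-score peak calling with gap-bounded peak extension; motif-phenotype
    association statistics (promoter occupancy, correlation screening,
    expression coherence, hypergeometric GO enrichment with child-term
    propagation, Fisher tissue enrichment); overlap-based evaluation of
    predicted modules against experimentally curated regulatory regions with
    a random-placement significance simulation; ortholog calling from
    reciprocal-best-hit tables and promoter extraction; and seeded synthetic
    data generators with planted ground truth so that every pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
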