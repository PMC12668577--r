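Package: asrkit
Title: Marginal Ancestral Sequence Reconstruction with FreeRate Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing functional transitions in protein families by
    marginal ancestral sequence reconstruction. Implements reversible
    amino-acid substitution models (LG-style exchangeabilities, empirical
    frequencies, FreeRate site-rate mixtures), Felsenstein pruning
    log-likelihoods, per-site posterior state probabilities at internal
    nodes, maximum-likelihood and AltALL ancestral sequences, ambiguity and
    posterior-probability summaries, signature-residue clade classification,
    expression-construct design by loop/tail grafting and validated point
    mutations, a gene-neighborhood enzyme-pairing statistic, and a forward
    simulator of sequence evolution along trees used for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    seqinr,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
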