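Package: sirmsd
Title: Structural Distortion Scoring and Seed-Mediated Off-Target Analysis
    for Chemically Modified siRNAs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the structural distortion that 2'-ribose chemical
    modifications (DNA, 2'-fluoro, 2'-O-methyl, 2'-O-methoxyethyl,
    2'-formamido, 2'-MTMM) impose on the siRNA guide strand seed region
    bound to Argonaute 2, using a nucleobase heavy-atom RMSD statistic
    (siRMSD) evaluated per nucleotide and over N-1/N/N+1 windows. Also
    provides the companion assay analytics: substantial off-target
    activity (SOA) from dual-luciferase reporter data, IC50 by log-scale
    bracketing interpolation, melting temperature by the second-derivative
    method with delta-Tm against an unmodified reference, seed-match
    classification of 3'UTRs with quantile-normalised expression
    fold-change shifts and Wilcoxon rank-sum testing, and Pearson
    correlation machinery with Fisher confidence intervals and regression
    confidence bands. A synthetic-fixture generator produces helical RNA
    coordinates, reporter tables, melting curves and expression matrices
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    limma,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
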