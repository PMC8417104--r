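Package: repfeat
Title: TCR-Beta Repertoire Diversity, Convergence and CDR3 Feature Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to compare T-cell receptor beta-chain (TCR-beta)
    repertoires between donor cohorts and sorted T-cell subsets.
    Implements UMI-based downsampling, per-V-segment diversity estimation
    (Chao1, normalized Shannon-Wiener evenness), convergent-recombination
    quantification, public-clonotype sharing, abundance-weighted CDR3
    physicochemical features (interaction strength, side-chain volume,
    charge, length, added nucleotides), within-stratum Z-scoring,
    rank-based multi-group inference (Kruskal-Wallis, Dunn post-hoc with
    Benjamini-Hochberg adjustment, Wilcoxon rank-sum) and principal
    component analysis, plus a seeded V(D)J recombination simulator that
    generates synthetic clonotype tables with controllable diversity,
    clonality, convergence and residue-composition bias. Reads and writes
    MiXCR-flavour and AIRR Rearrangement clonotype TSV tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
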