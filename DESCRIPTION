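Package: cepkit
Title: Motif-Based Discovery and Molecular Evolution of Plant CEP Peptide Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for surveying the C-TERMINALLY ENCODED PEPTIDE (CEP)
    gene family in plant genome assemblies. Builds hierarchically weighted
    position-specific probability matrices (PSPMs) of the 15-residue CEP
    domain, scans six-frame open reading frames with exact motif P-values,
    selects start codons by a pluggable secretion-signal scorer, and parses
    the canonical prepropeptide architecture (signal, variable region,
    domains, C-terminal extension). Downstream analyses cover maximum
    likelihood pairwise distances under the JTT amino-acid model,
    intra-organism pairwise distance (IOPD) diversity contrasts with
    rank-based Tukey tests, deterministic clustering reciprocal-best-hit
    orthology, sitewise dN/dS profiling by pathway counting with bootstrap
    intervals, and GC-content comparisons on the logit scale. A synthetic
    genome generator with planted ground truth makes every stage testable
    without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
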