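Package: connectocore
Title: Topological Characterization of Weighted Directed Connectomes
Version: 0.1.0
Authors@R: person("Network", "Neuro Tools", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the topological characterization of weighted directed
    mesoscale connectomes, such as tract-tracing derived cortico-cortical
    networks weighted by the fraction of extrinsic labeled neurons (FLNe).
    Implements degree-preserving (Maslov-Sneppen) rewired null ensembles with
    empirical significance testing, global graph statistics (strengths,
    weighted reciprocity, assortativity, Fagiolo directed-weighted clustering,
    characteristic path length under a logarithmic weight-to-length mapping,
    null-normalized small-world indices), multiscale directed-modularity
    community detection with Lancichinetti-Fortunato consensus clustering and
    normalized mutual information scale profiling, hub analysis (participation
    coefficients, out/in-strength ratios, rich-club curves against rewired
    nulls), a three-node motif census with canonical motif classes derived by
    exhaustive enumeration, and persistent homology of the clique complex
    under a decreasing-weight edge filtration (dimensions 0-2, with
    representative cycles and null comparison). A synthetic-connectome
    generator with distance-dependent weights and planted (optionally
    hierarchical) community structure makes the full pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
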