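# connectocore

Topological characterization of weighted directed connectomes in R.

Mesoscale tract-tracing connectomes — such as the cortico-cortical networks
assembled from retrograde tracer injections, weighted by the fraction of
extrinsic labeled neurons (FLNe) — are dense, directed, weighted graphs of
a few dozen cortical areas. `connectocore` implements the full analysis
stack used to characterize such networks:

- **IO**: labeled CSV/TSV matrices with a pairwise-complete node filter
  (untested entries are *missing*, distinct from "tested, absent" zeros),
  optional 3D injection-centroid coordinates, and the logarithmic
  weight-to-length mapping `l_ij = -ln(w_ij / w_max)`.
- **Null models**: Maslov–Sneppen double-edge swaps preserving the in- and
  out-degree sequences exactly; ensembles with deterministic seeding;
  empirical p-values `p = (r + 1)/(m + 1)`.
- **Global topology**: strengths `s_i^in = Σ_j w_ji`, `s_i^out = Σ_j w_ij`;
  weighted reciprocity `ρ = Σ(w_ij − w̄)(w_ji − w̄) / Σ(w_ij − w̄)²`;
  degree/strength assortativity over directed edges; the Fagiolo
  directed-weighted clustering coefficient; characteristic path length on
  the `−ln` length transform; null-normalized small-world indices
  `γ = C/C_rand`, `λ = L/L_rand`, `σ = γ/λ`.
- **Communities**: directed modularity
  `Q = (1/m) Σ_ij [A_ij − γ s_i^out s_j^in / m] δ(c_i, c_j)` maximized by a
  Louvain-style greedy optimizer, Lancichinetti–Fortunato consensus
  clustering over repeated runs, normalized mutual information, and a
  resolution sweep with plateau-based scale selection.
- **Hubs**: participation coefficients
  `p_i = 1 − Σ_c (s_i(c)/s_i)²` per partition with cross-resolution rank
  aggregation, out/in-strength ratios, and rich-club curves `φ(k)`
  normalized against the rewired ensemble.
- **Motifs**: the census of the 13 connected three-node digraph classes
  (classes derived by exhaustive enumeration with canonical labeling, in
  the Brain Connectivity Toolbox order — class 9 is the reciprocal
  two-chain, class 13 the fully reciprocal triangle) with two-tailed
  enrichment/depletion against nulls.
- **Persistent homology**: clique-complex filtration adding undirected
  edges in decreasing weight order, homology over GF(2) in dimensions 0–2
  with representative cycles, and cavity statistics against rewired nulls.
- **Synthetic connectomes**: geometric generators with exponential
  weight–distance decay, tunable reciprocity, lognormal weight noise, and
  planted (optionally hierarchical) community structure, so the entire
  pipeline is testable without external data.

## Worked example

```r
library(connectocore)

# a 55-node synthetic connectome emulating a tracer network:
# density 0.626, exponential weight-distance decay, high reciprocity
g <- generate_geometric(synthetic_spec(n = 55, target_density = 0.626, seed = 1))
g
#> <connectome_graph> 55 nodes, 1906 directed edges (density 0.642)
#>   with 3D coordinates

str(global_metrics(g), digits.d = 3)
#> $ density_directed      : num 0.642
#> $ density_undirected    : num 0.683
#> $ reciprocity           : num 0.725
#> $ assortativity_degree  : num -0.0572
#> $ assortativity_strength: num -0.0357
#> $ clustering_mean       : num 0.0332
#> $ char_path_length      : num 3.22

ens <- build_ensemble(g, n_members = 50, swaps_per_edge = 10, seed = 2)
sw <- small_world(g, ens)
sprintf("gamma = %.3f, lambda = %.3f, sigma = %.3f",
        sw$gamma_norm, sw$lambda_norm, sw$sigma)
#> "gamma = 1.109, lambda = 1.088, sigma = 1.020"

consensus_partition(g, gamma = 1, n_runs = 50, seed = 3)
#> <consensus_result> 50 runs -> 4 communities (gamma = 1, 3 iterations)

motif_significance(g, build_ensemble(g, 50, 10, seed = 4))
#> <motif_spectrum> 19126 connected triples
#>   M1   M2   M3   M4   M5   M6   M7   M8   M9  M10  M11  M12  M13
#>   38   78 1149   38   11   83 1241    4 7140  159   83 2378 6724
#> direction: depleted depleted depleted depleted depleted depleted depleted
#>            depleted enriched depleted depleted depleted enriched
```

Reading the output: the geometric graph is denser in reciprocal weight than
its degree-preserving rewirings (reciprocity 0.73), mildly small-world
(σ > 1), organizes into 4 communities at γ = 1, and its motif spectrum is
dominated by reciprocal chains (M9) and reciprocal triangles (M13) — the
same qualitative fingerprint reported for real cortico-cortical networks.

To run everything at once (all stages, report bundle with `summary.json`,
per-stage CSVs and a log):

```r
cfg <- analysis_config(input = "matrix.csv", out_dir = "report", seed = 42)
run_pipeline(cfg)
```

or from the shell:

```sh
Rscript inst/cli/connectocore.R run --input matrix.csv --out report --seed 42
```

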