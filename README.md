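# enzgraph

Structure-aware prediction of enzyme kinetic parameters in R.

The turnover number (kcat) and Michaelis constant (Km) decide whether
an enzyme is worth engineering: kcat is how many substrate molecules
one enzyme converts per second, Km the substrate concentration at
half-maximal rate. enzgraph is a library + CLI for predicting
log10-scale kcat and Km from three inputs — the enzyme sequence, its
3D backbone structure (PDB), and the substrate SMILES — aimed at
computational enzymologists building screening or directed-evolution
pipelines.

## What it computes

The structural core is a **residue graph**: residues are nodes
(secondary-structure one-hot, φ/ψ/ω sin/cos, normalized accessible
surface area, frame-projected side-chain direction), and directed
edges connect residues with Cα–Cα distance ≤ 10 Å (≤ 20 nearest
neighbors), carrying

> e_ij = ( PE(i−j), RBF(‖X_j−X_i‖), O_iᵀ (X_j−X_i)/‖X_j−X_i‖, q(O_iᵀO_j) )

— a sinusoidal positional encoding of the sequence offset, a Gaussian
radial-basis encoding of the distance, the inter-residue direction in
residue i's local frame O_i = [b, n, b×n], and the canonical
quaternion of the relative orientation. Every feature is invariant
under rigid motions of the structure.

An **edge-augmented graph-Transformer** encodes the graph: per head,

> α_ij = softmax_j ( ⟨W_Q h_i, W_K h_j + W_E e_ij⟩ / √d ),
> h_i′ = Σ_j α_ij (W_V h_j + W_E e_ij),

with residual + layer-norm attention and feed-forward blocks and mean
pooling into a graph embedding. Averaged, accumulated and normalized
attention weights give a per-residue **attention profile** used to
flag functionally critical (e.g. mutation) sites.

Sequence and substrate embeddings (1024-dim, pluggable backends with a
deterministic mock bundled) are reduced by a **residual MLP**, fused
with the structure embedding, and regressed with an
**extremely-randomized-trees** ensemble. Around this sit the curation
pipeline (validity filtering, dedup-with-max, unit + log10 transforms,
global-alignment identity, PDB chain selection > 90% identity,
resolution ≤ 3 Å, seeded 80/10/10 splits, similarity bins
0–40/40–80/80–99/99–100%) and evaluation metrics (R², PCC, RMSE, MAE)
with grouped reports.

## Worked example

```r
library(enzgraph)

# build a 12-residue ideal helix, featurize, encode
strc  <- make_helix_fixture(12, "helix")
graph <- featurize(strc)
graph
#> <residue_graph> 12 nodes, 90 directed edges
#>   node feature dim: 13  edge feature dim: 39

enc  <- encode_graph(graph, seed = 7)
prof <- attention_profile(enc)
head(prof, 3)
#> # A tibble: 3 x 2
#>   residue weight
#>     <int>  <dbl>
#> 1       1 0.0630
#> 2       2 0.0635
#> 3       3 0.0732
```

12 residues at helical spacing all fall within the 10 Å cutoff of most
of the chain, giving 90 directed edges; the profile is the normalized
incoming attention per residue (sums to 1).

```r
# synthetic dataset with known signal in all three blocks
syn <- synthetic_kinetics(500, seed = 1, noise_sd = 0)
set.seed(101); idx <- sample.int(500)
model <- fit_kinetics(syn$rows[idx[1:400], ], n_trees = 300, seed = 1)
preds <- predict(model, syn$rows[idx[401:500], ])
grouped_report(syn$rows$target[idx[401:500]], preds,
               groups = rep("held-out", 100))
#> # A tibble: 2 x 6
#>   group_label     n    r2   pcc  rmse   mae
#> 1 held-out      100 0.949 0.983 0.380 0.244
#> 2 all           100 0.949 0.983 0.380 0.244
```

Held-out R² ≈ 0.95 on noiseless synthetic data says the fused
pipeline recovers a signal planted across sequence, structure and
substrate blocks; `rmse`/`mae` are in log10 units of the kinetic
value.

A command-line interface wrapping these functions ships at
`inst/cli/enzgraph.R` (subcommands `fixtures`, `parse`, `featurize`,
`encode`, `attention`, `prepare`, `evaluate`).

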