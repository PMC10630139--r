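# sccot — counterfactual cell matching by entropic optimal transport

Perturbation scRNA-seq experiments measure control and treated cells, never
the same cell under both conditions. Estimating what a *given* cell would
have looked like under the other condition — its counterfactual — requires
separating the variation cells carry independently of the treatment
(cell state, cell cycle, continuous programs: the confounders) from the
variation the treatment induces. `sccot` is for computational biologists who
want per-cell, per-gene treatment effects, synergy scores for combinatorial
treatments, and attribution of heterogeneous responses to underlying cell
states, without collapsing their data to pseudobulk averages.

## Method

Given a cells × genes matrix and a binary treatment label *z*:

1. **Decompose.** PCA of log-normalized expression, then ICA of the PC
   embedding: *S* = *X B*, with sources *S* and unmixing *B*.
2. **Filter.** Each component is scored against *z* with the Chatterjee
   rank coefficient ξₙ (tie-aware form, since *z* is binary:
   ξ = 1 − n Σ|r᷈ᵢ₊₁ − rᵢ| / (2 Σ lᵢ(n − lᵢ))). Components with ξ below a
   threshold *d* form the confounder subspace *Sᶜ*.
3. **Match.** Entropic optimal transport between control and treated cells
   in *Sᶜ*: M = diag(u) · exp(−D²/s) · diag(v), solved by Sinkhorn–Knopp
   scaling to prescribed marginals (uniform, or reweighted by confounder
   labels).
4. **Estimate.** Each control cell's counterfactual treated profile is its
   row-normalized plan average of treated cells;
   ITEᵢ = x̂ᵢ⁽¹⁾ − xᵢ.

A reweighted variant (`balance = "auto"`) handles treatment-induced
differential abundance: treated cells are aligned to their *k* nearest
control neighbours, the aligned set is Leiden-clustered, each cluster is
subsampled to equal condition counts, and the ICA filter is fitted on the
balanced subsample before being applied to all cells.

Downstream: the synergy matrix Ψ = D_AB − (D_A + D_B) for combinatorial
treatments, per-gene/per-cell synergy scores, coarse-grained
response-cluster × control-cluster matching, the causal regression
X = αz + βc + γcz + const with an ℓ₂ ratio for confounder-specific effects,
and Wilcoxon signed-rank DE gene selection on the matched effects. A
gamma-Poisson benchmark generator with ground-truth labels and the
batch-mixing / cluster-preservation metrics (ASW, PCR, ARI) make the whole
system testable end to end with no external data.

## Worked example

```r
library(sccot)

sim <- simulate_dataset(simulation_config(n_cells = 1000,
  n_confounder_genes = 300, n_response_genes = 150, seed = 1))
fit <- sccot(sim$dataset, rank = 15, threshold = 0.05,
             smoothness_per_dim = 1e-5, seed = 1)
fit
```

```
Counterfactual OT matching fit (sccot)
  cells: 478 control / 522 treated; genes: 450
  components: 15 total, 13 confounder, 2 treatment-associated (threshold 0.05)
  transport: converged after 10 iterations; ITE 478 x 450 (expression, counterfactual_for_control)
```

Two components carry the treatment signal (the response-cluster signatures);
the other 13 — cell states, programs, noise directions — are used for
matching. The ITE matrix has one row per control cell. DE selection on the
matched effects:

```r
head(select_de_genes(ite(fit)), 3)
```

```
        gene     effect median_effect            p pass
335 resp_g35 -0.8117863    -0.7885913 1.074879e-64 TRUE
347 resp_g47  0.7935384     0.7916599 1.432233e-64 TRUE
390 resp_g90 -0.8068058    -0.8786893 9.827045e-60 TRUE
```

The top genes are response-block genes (as constructed), with matched
log-expression differences and exact/approximate signed-rank p-values; the
`pass` flag applies both the p < 1e-5 and the |effect| > 0.5 thresholds.
Recovery of the planted response structure:

```r
tr <- sccot(sim$dataset, rank = 15, threshold = 0.05,
            smoothness_per_dim = 1e-5, seed = 1,
            direction = "counterfactual_for_treated")
ari_ite(tr$ite, sim$true_response_cluster[tr$treated_index], seed = 1)
#> [1] 0.9362443
```

An adjusted Rand index of 0.94 means Leiden clusters of the estimated
per-cell effects almost exactly recover the ground-truth response clusters
(at the full 5,000-cell default the recovery is essentially perfect).

A command-line wrapper for shell pipelines lives at
`inst/cli/sccot.R` (subcommands `simulate`, `run`, `synergy`, `attribute`,
`benchmark`).

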