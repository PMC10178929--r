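---
title: "OmicsBN: model, priors and sampler"
author: "OmicsBN authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{OmicsBN: model, priors and sampler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model implemented by OmicsBN, the
meaning and defaults of every tuning parameter, what the synthetic-data
generator does and does not cover, and the numerical choices that affect
results.

## 1. The layered Bayesian network

Nodes come from three omics layers: gene expression (GE), copy number
(CNV, node ids prefixed `cnv_`) and methylation probes (METH). The
*candidate edge set* — the universe of edges the sampler may ever
propose — contains

* every ordered pair of distinct GE genes,
* the cis edge `cnv_g -> g` for each gene with copy-number data,
* `probe -> gene(probe)` for each retained methylation probe.

GE→CNV and GE→METH edges are excluded and CNV/METH nodes take no parents,
so cycles can only arise inside the GE layer. Per-layer fan-in limits
bound the number of parents of a GE node (defaults: 3 GE, 1 CNV, 2 METH;
the GE limit counts only GE parents).

### Methylation probe filtering

Before network inference, each probe is regressed against its mapped
gene's expression (`filterMethProbes()`). With Pearson correlation r on n
samples, the probe's R² = r² and the slope p-value comes from
t = r·sqrt((n−2)/(1−r²)) on n−2 degrees of freedom — identical to
`summary(lm(...))`. A probe is retained when R² ≥ `rSquaredThres`
(default 0.3) and p ≤ `pValThres` (default 0.05). Zero-variance columns
score R² = 0, p = 1 and are dropped with a warning. Note that a probe that
is a genuine *cause* of expression can still show small marginal R² when
the gene has several other parents; aggressive R² thresholds therefore
trade specificity for sensitivity (see §5).

## 2. The BGe score

Data are modelled as jointly Gaussian. For a node set A of size l out of d
variables, the marginal likelihood under the normal-Wishart prior with
mean ν, precision-scale α_μ, degrees of freedom α_w and scale matrix T is

```
log ml(A) = −(lN/2)·log π + (l/2)·(log α_μ − log(α_μ + N))
          + Σ_{j=1..l} [ lΓ((N + a_w + 1 − j)/2) − lΓ((a_w + 1 − j)/2) ]
          + (a_w/2)·log det T_A − ((N + a_w)/2)·log det R_A
```

with a_w = α_w − d + l and

```
R = T + S_N + (N·α_μ/(N + α_μ)) (ν − x̄)(ν − x̄)ᵀ
```

(S_N the centered scatter matrix; subscript A = restriction to A's rows
and columns). The local score of node i with parent set P is
`log ml(P ∪ {i}) − log ml(P)`, and the network score is the sum of local
scores. Defaults (`bgeHyperparameters()`): ν = column means, α_μ = 1,
α_w = d + 2 and T = α_μ(α_w − d − 1)/(α_μ + 1)·I = 0.5·I, the
standard score-equivalent choice. The suite
verifies this closed form against an independent sequential
multivariate-t predictive oracle to ~1e−14 and score equivalence across
all 185 Markov equivalence classes on 4 nodes to ~1e−14.

## 3. The biological prior and its empirical completion

Each candidate edge e carries a belief b_e ∈ [0,1] with a provenance tag:

| provenance  | source                              | value          |
|-------------|-------------------------------------|----------------|
| `curated`   | prior-knowledge table, `present`    | 0.99           |
| `curated`   | prior-knowledge table, `absent`     | 0.01           |
| `tf_target` | TF→target table (if not curated)    | 0.99           |
| `default`   | nothing known                       | 0.5            |
| `empirical` | phase-1 edge frequency              | clamped [0.01, 0.99] |

The structure prior is `log p(G) = −β·E(G) − log Ẑ(β)` with energy
`E(G) = Σ_e |b_e − a_e|` (a = adjacency indicator) and the edge-factorized
pseudo partition function

```
Ẑ(β) = Π_e [ exp(−β·b_e) + exp(−β·(1 − b_e)) ].
```

Ẑ ignores the acyclicity constraint; it is exact for the prior viewed over
independent edge indicators and only enters the β move, where it makes
moves between β values well defined. β is sampled by Metropolis-Hastings
with a symmetric uniform proposal (half-width 0.5) reflected at 0 and
`betaMax` (default 10), accepted with
`min(1, exp(−(β′−β)·E)·Ẑ(β)/Ẑ(β′))`, once per structure sweep (every
d structure proposals). Two consequences are used as unit tests: with
b ≡ 0.5 every β proposal is accepted and the chain is uniform on
[0, betaMax] in the long run, and a structure strongly contradicting a
concentrated prior drags β toward 0.

## 4. Two-phase MCMC

Structure proposals are the classic MC3 single-edge moves — add, delete,
reverse — drawn uniformly from the *legal* neighborhood (acyclic, within
fan-in, inside the candidate set), accepted with
`min(1, exp(Δ log BGe + Δ log prior) · |N(G)| / |N(G′)|)`. Only affected
local scores are recomputed (one child for add/delete, two for reverse).

`runMcmc()` runs two phases:

1. **Adaptation** — `round(phase1Fraction · totalIterations)` iterations
   (default fraction 0.5) with the curated/default prior matrix. Its edge
   frequencies (own burn-in = half of phase 1, same thinning) replace all
   `default` beliefs via the clamp rule above; `curated` and `tf_target`
   entries are never overwritten. `phase1Fraction = 0` skips adaptation
   and keeps the input prior unchanged.
2. **Sampling** — the full `totalIterations` from the phase-1 final
   structure with the completed prior. The returned trace is phase 2's.

A snapshot of the structure is recorded at every iteration t with
t > burnIn and (t − burnIn) mod thin = 0, so
`totalIterations = burnIn + thin` yields exactly one snapshot. A single
seeded RNG stream drives move choice, acceptance and β proposals;
identical seeds give bit-identical traces. Interrupted runs persist a JSON
checkpoint (doubles serialized exactly; RNG state included) and resuming
reproduces the uninterrupted run bit for bit.

The inner loop is C++ (Rcpp); cycle checks use 64-bit bitsets over the GE
subgraph, which caps the GE layer at 64 genes.

## 5. Posterior summaries

* **Edge weights** are empirical frequencies of each directed candidate
  edge over retained snapshots.
* **Thresholding** keeps edges at or above either an absolute cutoff or a
  quantile of the nonzero weights (default: 0.75-quantile, type-7).
* **CPDAG labelling**: v-structures are oriented and the Meek rules
  applied to fixpoint; reversible edges are reported undirected and carry
  the skeleton weight (sum of both direction frequencies). Cross-layer
  edges are compelled by construction. Agreement with the
  skeleton + v-structure characterization of Markov equivalence is tested
  exhaustively on all 543 DAGs over 4 nodes.
* **Convergence** is assessed by mean-shift binary segmentation of the
  post-burn-in log-posterior at snapshot resolution with penalty
  `2·log(n)·σ̂²`, σ̂² estimated from first differences, and minimum segment
  length `minseglen/thin` snapshots. The chain is flagged converged when
  no changepoint is found. Because σ̂² from first differences
  underestimates the marginal variance of an autocorrelated chain, the
  scan is conservative: it can flag small plateau changes in healthy
  chains, so treat "not converged" as a prompt to inspect the trace plot,
  not as a verdict.
* **Exports**: TSV (lossless round trip through `importNetwork()`),
  GraphML (via igraph) and SIF.

## 6. The synthetic-data generator

`generateTrueNetwork()` draws a random topological order over `nGenes`
genes, flips independent coins at `edgeProb` for each earlier-to-later
pair (suppressed once a child has `fanInMax` GE parents), attaches a cis
CNV parent per gene with probability `pCnv`, and adds `probesPerGene`
causally linked plus `noiseProbesPerGene` causally unconnected (but
annotated) METH probes per gene. Coefficients are ±Uniform[0.5, 1.5] and
node noise standard deviations Uniform[0.5, 1]. `simulateDataset()`
evaluates the linear-Gaussian structural equations in topological order
with standard-normal roots. `corruptPrior()` emits a prior-knowledge table
with a chosen fraction of true GE→GE edges and, optionally,
misinformation rows.

The generator covers linear effects with moderate signal-to-noise only;
it makes no attempt at realistic methylation beta-value distributions,
batch effects or nonlinearities. One practical consequence, measured over
five generator-default studies (10 genes, `edgeProb` 0.2, CNV on all
genes, one linked and one noise probe per gene, n = 200): ranking
candidate edges by posterior weight achieves mean AUROC ≈ 0.94 against
the true adjacency and an R² ≥ 0.5 probe filter removes *all* noise
probes, but that same filter keeps only ~16% of the causally linked
probes, because a linked probe's marginal R² is c²/Var(gene) ≈ 0.1–0.3
when the gene has several other parents. Filter thresholds should be
chosen with this trade-off in mind (the package default is R² ≥ 0.3).
These numbers come from the seeded runs in `scripts/acceptance.R` and the
test suite; re-run either to reproduce them.

## 7. Numerical choices

* Determinants via Cholesky with a single retry after adding 1e−8 jitter;
  failure raises an error rather than silently regularizing further.
* Local scores are memoised (node, sorted parent set); the C++ sampler
  uses a compact byte-packed key for graphs with ≤ 250 nodes and ≤ 7
  parents, falling back to direct evaluation otherwise.
* Checkpoints store all accumulated floating-point state with "%.17g"
  precision so that resumed runs are bit-identical.
* Incremental score accumulation over hundreds of thousands of moves
  drifts from a full rescore only at the ~1e−12 level; the suite enforces
  1e−9.

## 8. Limitations

* Gaussian likelihood only; no discrete or zero-inflated models.
* The pseudo partition function Ẑ ignores acyclicity (it normalizes a
  product of independent edge terms), so sampled β values should be read
  as a data-driven trust scale, not as a calibrated posterior over β.
* Single chain; convergence diagnosis is post-hoc. For replicate-chain
  comparisons run `runMcmc()` with different seeds.
* The candidate space hard-codes the layer directionality of the model;
  feedback loops and GE→METH regulation are out of scope.
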