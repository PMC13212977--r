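---
title: "Pathway crosstalk networks for drug response prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway crosstalk networks for drug response prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The prediction problem

`pcndrp` predicts the natural-log half-maximal inhibitory concentration,
ln(IC50) in micromolar, of a drug in a cancer cell line, from (a) the cell
line's transcriptome and (b) the drug's molecular structure. The package's
premise is that a transcriptome is better represented to a regression model
as a small graph of interacting *pathways* than as tens of thousands of
individual genes: pathway-level features suppress technical variation
between expression platforms (batch effects) while preserving the biology
that determines drug sensitivity, and the *crosstalk* between pathways --
which pathways sit near each other in interaction networks, and which rise
and fall together -- carries signal that per-pathway scores alone do not.

# Pathway activity scoring

Expression is first normalized (`normalize_expression()`: log2(x+1) for
TPM-like counts, arcsinh, per-sample or per-gene z-scores) and then
summarized per pathway and sample (`score_pathways()`). The built-in
scorers are rank-based and operate on one sample at a time:

* **singscore** (default). Genes are ranked 1..N within the sample
  (average ranks on ties). For a gene set of size n with mean member rank
  m, the score is the mean rank rescaled between its theoretical extremes,
  `(m - (n+1)/2) / (N - n) - 0.5`, lying in [-0.5, 0.5]. Because it uses
  only within-sample ranks it is invariant under any strictly monotone
  transform of the expression values -- the property that makes it robust
  to cross-platform scale differences, verified directly in the test
  suite.
* **ssgsea**: the single-sample weighted Kolmogorov--Smirnov enrichment
  statistic (rank weights raised to 0.25), with the conventional global
  range normalization (`ssgsea_nonorm` omits it).
* **gsva**: a built-in population-referenced scorer. Each gene is first
  replaced by its ECDF value across the sample population -- genes are
  scored as over- or under-expressed relative to the cohort, which removes
  per-gene location differences between separately scored datasets; per
  sample, genes are then ranked with symmetric weights `|rank - N/2|` and
  the set score is the signed sum of the extreme deviations of the
  weighted KS random walk (the max-deviation-difference convention). This
  population referencing is what makes the scorer robust to per-gene batch
  shifts -- and also what makes it unreliable on very small or biased
  cohorts, since every gene is judged against the sample population. An
  external implementation can replace the built-in via
  `register_scoring_backend("gsva", ...)`. The benchmark pipeline uses
  these scores as the model's cell features; singscore is the per-sample
  alternative when no cohort is available.

Scores destined for the model are standardized per pathway by a robust
median/IQR scaler (`fit_scaler()`/`apply_scaler()`), with quantiles
computed by linear interpolation (the type-7 convention) and z-scores
clamped to [-10, 10]. Pathways with zero IQR across the training samples
get unit scale rather than being dropped, so the pathway order stays
aligned with the graph described next. The scaler is fitted on training
cell lines only and then applied to any query data, which is how external
datasets are mapped into the training feature space.

# The pathway crosstalk network (PCN)

Cell lines are encoded over a fixed directed graph with one node per
pathway and three edge types ("relations"):

1. **ppi** -- proximity in a protein--protein interaction network,
2. **grn** -- proximity in a gene regulatory network,
3. **corr** -- correlation of pathway activity scores across cell lines.

For the two network relations, proximity of pathways A and B is the
network separation score
`s_AB = <d_AB> - (<d_AA> + <d_BB>)/2`,
where `<d_XY>` is a mean of shortest-path hop distances between the gene
sets in the (undirected) network. Low or negative values mean the two
pathways occupy overlapping network neighborhoods. Two conventions for the
mean are implemented (`separation_score(convention=)`):

* `"nearest"` (default): each gene contributes its distance to the nearest
  gene of the opposite set (for `<d_AB>`) or to the nearest *other* member
  of its own set (for `<d_XX>`; singletons contribute 0). This is the
  convention of the disease-module separation literature from which the
  score originates, and shared genes make `<d_AB>` = 0 contributions.
* `"all_pairs"`: the plain mean over all pairs.

Both satisfy the verbal definition of the score; both are checked exactly
against a brute-force BFS oracle in the tests, and the choice is a config
switch throughout. If no connected gene pair exists within or between the
sets the score is undefined (`NA`), never an exception.

Each relation is then trimmed to a K-nearest-neighbor graph
(`build_knn_relation()`, K = 5 by default): each pathway points to the K
pathways with the lowest separation scores (or highest correlations for
the corr relation). Undefined scores are excluded from ranking, never
imputed; if fewer than K scored candidates exist, the shortfall is filled
by the highest gene overlap ratios (Jaccard index, `overlap_ratio()`).
Correlations are essentially never missing, so the corr relation uses no
fallback. Ties break lexicographically by pathway id, which makes graph
construction fully deterministic. Because "A's nearest neighbors" is not a
symmetric relation, the PCN is directed: an edge A -> B does not imply
B -> A, and the tests construct an explicit witness of this asymmetry.

`perturb_pcn()` provides the structural null model used in ablations: a
degree-preserving double-edge swap per relation (delegated to igraph's
`keeping_degseq` rewiring), which preserves every node's in- and
out-degree while destroying the specific connections.

# Drug graphs

SMILES strings are parsed with OpenBabel (via ChemmineR) into heavy-atom
graphs (`featurize_drug()`). Atom feature rows are 85-dimensional:
element one-hot over 53 symbols plus an "unknown" slot, heavy-atom degree,
formal charge, a derived hybridization class, chirality (read from the
SMILES bracket annotations, since 2-D MOL blocks carry no parity), an
implicit-hydrogen count, ring and aromaticity flags, and the atomic mass
scaled by 1/100 to keep it commensurate with the one-hot blocks. Bond
rows are 10-dimensional: bond type one-hot (single/double/triple/
aromatic), a conjugation flag, a ring flag, and a stereo one-hot. Every
chemical bond is stored as two directed edges. The exact block layout is a
declarative `feature_scheme()` object, so alternative encodings are
possible (non-standard widths are flagged); the shipped default is a
faithful reconstruction of the named feature categories, not a byte-level
copy of any particular toolkit's table. Hydrogens stay implicit and salt
fragments are kept as disconnected components. `morgan_fingerprint()`
exposes circular fingerprints (OpenBabel ECFP2/4/6 folded to 128--1024
bits) for fingerprint-based baselines.

# Response labels

`average_duplicates()` collapses repeated (cell, drug) measurements to
their mean and reports the duplicate count, the RMSD between duplicated
values and their group means, and the correlation between duplicates and
(repeated) group means -- the only reading of "deviation between
duplicates and their averages" that produces one scalar per dataset.
`merge_gdsc()` unions two screen releases with the newer release winning
conflicts (its wider concentration range gives more precise IC50
estimates). External activity tables are converted to ln(IC50 uM) by
`convert_external_ic50()`; `filter_capped()` removes right-censored
records whose raw IC50 equals the assay cap. Within-release duplicate
averaging happens before the cross-release merge.

# The regression model

The network (`model_config()`, `init_model()`) has three parts.

**Cell encoder.** A three-layer relational graph convolution over the PCN.
The input node feature is the single scaled pathway score. Layer l with
hidden width 8 computes, for node i,
`h_i = ELU( W_self x_i + sum_r mean_{j -> i in r} W_r x_j + b )`,
with one weight matrix per relation r plus a self term (so isolated nodes
still update; with only three relations no basis decomposition is
needed). Dense cross-layer concatenation feeds each layer the
concatenation of the raw input and all previous layer outputs --
mitigating over-smoothing -- so the per-pathway output is the
concatenation of all three hidden layers, 24 dimensions. All pathway
embeddings are then *flattened* into one long vector (pathways x 24;
7008 for a 292-pathway collection) rather than pooled, preserving pathway
identity, and one fully connected layer maps it to a 256-dim cell
embedding.

**Drug encoder.** A three-layer, four-head graph attention network over
the atom graph, hidden width 128 per layer, with the same dense
concatenation. Attention logits combine source, target and projected bond
features through per-head attention vectors with a LeakyReLU(0.2); the
softmax runs over each atom's incoming edges (self-loops added so lone
atoms attend to themselves). Heads are concatenated and projected back to
the layer width -- the arrangement under which the stated layer widths
compose. The per-atom concatenation across layers is 3 x 128 = 384 under plain
concatenation; since other width conventions exist for this final
dimension, it is configuration-driven with 384 as the default. Global max pooling over atoms and one fully connected
layer yield the 256-dim drug embedding.

**Head.** The two embeddings are concatenated (512) and passed through two
fully connected layers (512 -> 128 -> 1, ReLU, dropout 0.2 in training) to
the scalar ln(IC50) prediction.

All of this runs on a small reverse-mode automatic differentiation engine
written for this package (R/autodiff.R): a tape of matrix operations
(matmul, gather/scatter, segment softmax, grouped max, block reshapes)
with hand-written adjoints. The engine is validated by a finite-difference
gradient check over randomly sampled parameters of the full model
(relative error < 1e-4 demanded; observed ~1e-8), and the encoders are
additionally checked for the symmetries the architecture promises: drug
embeddings invariant to atom renumbering (up to floating-point
reassociation, so asserted at 1e-10 rather than bitwise) and cell
activations equivariant under consistent pathway relabeling.

**Training** (`train_model()`) is minibatch Adam on mean squared error,
early-stopped on validation MSE with patience 10 within a 300-epoch cap;
the best-validation parameters are returned. Learning rate 1e-3 and batch
size 1024 are the package defaults: they were fixed once during
development as the configuration in which full training runs converge
comfortably within the epoch cap under this engine's throughput (at a
1e-4 rate, convergence at these problem sizes does not complete within
the cap). Runs are deterministic given the seed on a fixed thread count.

**Attribution.** `grad_cam()` explains a single prediction by
backpropagating it to the first cell-layer activation matrix A
(pathways x channels); the first hidden layer is used because its
receptive field is still pathway-local. The default combination is
per-node gradient weighting, `importance_p = ReLU(sum_k dy/dA[p,k]
A[p,k])`, in the *sensitivity* direction (gradients of the negated
prediction): this package's head consumes a flattened, position-specific
pathway embedding, so the gradient pattern over pathways carries the
localization, and the textbook Grad-CAM step of averaging gradients over
positions into channel weights (`alpha_k = mean_p dy/dA[p,k]`) -- which
presumes channels are shared feature detectors, as in CNNs -- pools that
information away. On the synthetic benchmark, where each drug's causal
pathways are known, channel pooling ranks causal pathways no better than
chance while node pooling recovers a causal pathway in the top five for
the large majority of sensitive pairs; both rules are available
(`pooling = "node"/"channel"`, `target = "sensitivity"/"response"`), and
the channel rule is verified against a closed-form surrogate whose output
is a fixed linear functional of the activations.

# Evaluation scenarios

`make_splits()` builds the four blinding scenarios. Unblinded: response
pairs are dealt per cell line round-robin into 10 parts (so each cell is
represented in every part, and drugs approximately so), and fold f uses
part f for testing, the cyclically next part for validation, the rest for
training (8:1:1). Cell-blind and drug-blind partition the *entities* into
10 parts the same way, pairs following their entity. Strict-blind
partitions cells and drugs into 5 parts each; each of the 25 folds tests
on one (cell-part x drug-part) block, validates on the diagonally next
block -- a deterministic choice that realizes a 3:1:1 ratio per axis; any
off-diagonal block would satisfy the ratio equally, and ours is simply
fixed -- and trains on the remaining 3 x 3 blocks, discarding pairs that
cross blind boundaries. Disjointness of the blinded entities, exact fold
counts (10/10/10/25), and exactly-once test coverage are property-tested
over many seeds.

Metrics (`compute_metrics()`) are RMSE, Pearson and Spearman correlations,
overall or per cell/drug (entities with fewer than 3 pairs are excluded
from per-entity rank correlations). Model comparisons use one-tailed
Mann--Whitney tests (`compare_models()`; exact when the combined sample is
at most 20 without ties, normal approximation with tie correction
otherwise; two identical constant samples report p = 0.5 with a flag).
`responder_analysis()` computes the responder-vs-non-responder effect size
(difference of mean predictions) with the one-tailed test that responders
score lower. `entity_statistics()` reports per-entity count, mean, sample
SD, Sarle's bimodality coefficient with the small-sample correction
`b = (g1^2 + 1) / (g2 + 3(n-1)^2 / ((n-2)(n-3)))`, and density coverage as
the overlap coefficient between the entity's and the global Gaussian
kernel densities (Silverman bandwidth, common 512-point grid) -- the
factor-analysis literature this follows does not print its formulas, so
these standard definitions are documented choices.

# The synthetic world

Because the package must be testable end to end without downloads,
`gen_world()` builds a complete synthetic study with known ground truth:

* a scale-free gene network (Barabási--Albert, m = 3) -- biological
  interactomes are heavy-tailed;
* pathways sampled as connected network neighborhoods (10--20 genes, with
  a controlled overlap fraction), so that separation scores are
  informative, plus a `scrambled_pathways` switch for the null case;
* latent pathway activities with factor-induced correlation across
  pathways, unit variance per pathway;
* log-scale expression: a stable per-gene baseline abundance (SD 3 --
  real log-TPM spans several units between genes, the structure rank
  methods rely on) plus the mean activity of the gene's pathways, a
  per-batch gene-level offset (SD 1, a platform shift) and per-measurement
  technical noise (SD 0.2); genes outside every pathway carry
  cell-intrinsic standard-normal variation shared across batches (a cell
  line's profile is a property of the cell; only measurement noise differs
  between platforms);
* drugs drawn from a bundled vocabulary of several hundred curated,
  parseable SMILES; each drug gets an intercept and a sparse effect
  vector beta over at most 3 causal pathways, |beta| in 0.5--1.5;
* responses `ln_ic50 = mu_d + beta' activity + N(0, 0.3)` over half of all
  (cell, drug) pairs (a monotone tanh warp is available as a robustness
  switch).

The default benchmark world has 600 genes, 30 pathways, 200 cells and 50
drugs (about 5,000 measured pairs); these are the problem sizes at which
every end-to-end result in the tests and the acceptance script is
computed, and the `tiny`/`small`/`paper_shaped` presets bracket it. What
this world emulates is the *statistical* structure the method assumes:
pathway-mediated expression, cross-platform batch shifts, and
pathway-dependent drug response. What it does not emulate: realistic
transcript count distributions, realistic chemistry--activity
relationships (drug structures are decorrelated from their simulated
effects, so nothing can be concluded about chemical generalization beyond
what the blinding scenarios measure), or clinical heterogeneity. Passing
tests therefore demonstrate that the machinery recovers known structure
under the model's assumptions, not that it attains any particular accuracy
on real pharmacogenomic screens.

On this world the package's end-to-end checks assert the qualitative
pattern expected of the method: unblinded test RMSE well below the
response SD (<= 0.8 x SD), cell-blind RMSE better than the global-mean
baseline, strict-blind at least as hard as unblinded, Grad-CAM top-5
attributions containing a causal pathway for at least 60% of sensitive
pairs, and rank-based pathway scoring (as well as per-batch gene-wise
standardization) shrinking the normalized within-cell cross-batch
distance below 25% of its unnormalized value, with per-sample
standardization clearly weaker. Distances are compared as the ratio of
within-cell cross-batch to between-cell within-batch distance because raw
distances are not commensurable across feature spaces of different
dimension. Gene-wise standardization is applied within each batch
separately -- the only reading under which it can remove per-batch gene
shifts, and the way it is used on separately sourced datasets.

# Numerical choices and degenerate inputs

* Quantiles: type 7 (linear interpolation) everywhere.
* Tied ranks: average ranks, in scoring and in Spearman correlation.
* Zero-variance pathways: unit scale in the scaler (flagged); `NA`
  correlations (warned) excluded from neighbor ranking.
* Zero-variance truth in metrics: RMSE reported, correlations `NA`.
* Attention softmax: stabilized by subtracting the per-segment maximum
  (treated as a constant, which leaves the softmax gradient exact).
* Edgeless graphs: the relational convolution degrades to per-node
  transforms; single-atom drugs attend to themselves via self-loops.
* KNN ties: lexicographic pathway id; `NA` scores excluded, fallback
  fills only the shortfall.
* Early stopping requires improvement > 1e-9 to reset patience.

# Limitations

* The built-in gsva-style scorer implements the population-referenced
  scoring family, not any specific release of the reference
  implementation; a registered backend takes precedence when exactness
  against a particular version matters.
* Chirality and bond stereo are reconstructed from SMILES annotations and
  MOL wedge codes; molecules whose stereo OpenBabel does not write survive
  with "none"/"other" flags.
* The drug encoder's final per-atom width is the plain 384-dim
  concatenation; all layer widths are configurable when another
  convention is wanted.
* The autodiff engine is single-threaded R + BLAS; it is sized for
  hundreds of cells and drugs, not for full-screen training corpora.
* Identifier harmonization across cell-line naming systems is left to a
  user-supplied mapping; no alias resolution is attempted.
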