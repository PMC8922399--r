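---
title: "Multitask attentive graph QSAR for kinase selectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitask attentive graph QSAR for kinase selectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

The four Janus kinase isoforms (JAK1, JAK2, JAK3, TYK2) share a highly
conserved ATP pocket, so a compound potent on one isoform is often potent on
the others — and clinically useful JAK inhibitors need *selectivity*, not just
potency. Public activity data for the family is abundant but lopsided: tens of
thousands of IC50 measurements for JAK1/JAK2, far fewer for JAK3 and TYK2, and
most compounds are measured on only a subset of the isoforms. `mtqsar`
implements a complete workflow for this setting: a single graph-attention
regressor with one output head per isoform predicts all four pIC50 values at
once, so the sparsely measured isoforms borrow statistical strength from the
densely measured ones, and the difference between a compound's four predictions
is a direct readout of its predicted selectivity profile.

# Data model and curation

Raw input is a long table of (SMILES, target, IC50 in nM) rows pooled from
heterogeneous sources. Curation proceeds in fixed order:

1. **Standardization** (`standardize_smiles()`): structure normalization,
   largest-fragment desalting, charge neutralization, canonical SMILES. The
   canonical string is the compound identity. Unparseable rows are logged and
   dropped, never silently discarded. The chemistry itself is performed by
   RDKit behind a batch JSON interface (`inst/python/chem_backend.py`); the R
   functions own the contracts, the backend owns the perception.
2. **Deduplication** (`merge_duplicates()`): one record per canonical SMILES;
   when a compound has several measurements on the same target, the *lowest*
   IC50 is kept. The rule is applied per target because records are
   multi-target.
3. **pIC50 conversion**: `pIC50 = 9 - log10(IC50/nM)`, i.e. the negative
   decadic logarithm of the molar concentration. On this scale 1 nM is 9 and
   the conventional 1 uM activity cutoff is 6. We use the molar convention
   throughout because activity thresholds and reported value ranges in this
   field only make sense on it.
4. **Splitting** (`split_dataset()`): a seeded random 8:1:1
   train/validation/test partition. Validation and test sizes are the rounded
   shares; the remainder goes to training, so the partition is exhaustive and
   disjoint by construction.

# The network

Molecules become attributed graphs (`mol_to_graph()`): atoms carry one-hot
blocks for element, degree, formal charge, hybridization, aromaticity,
attached-hydrogen count and tetrahedral chirality tag; bonds carry bond type,
conjugation, ring membership and E/Z stereo. Stereoisomers therefore featurize
differently — the model can in principle distinguish enantiomer pairs and
cis/trans isomers. The schema is declarative (`default_feature_schema()`) and
its identity string is stored in every checkpoint; a checkpoint refuses to load
under a different schema.

Each attentive layer updates every atom state \(h_k\) as follows. For each
neighbor \(j\) (with bond features \(e_{kj}\) concatenated to the neighbor
state), an attention logit

\[ \ell_{kj} = \mathrm{LeakyReLU}\!\left(\vec a^{\,T}\,[W_s h_k \,\|\, W_n (h_j \| e_{kj})]\right) \]

is normalized by a softmax over the neighbors of \(k\), the attention-weighted
neighbor messages are summed into a context vector, and a GRU cell updates
\(h_k\) from that context. After the configured number of layers (default 2),
an attentive readout builds a molecule super-node: initialized as the mean
atom state, it attends over all atoms for a configured number of timesteps
(default 2), each timestep refining the super-node with a GRU. Per-target
linear heads on the shared embedding produce the pIC50 vector. A
single-target configuration is exactly the first head of the multitask
configuration drawn from the same seed (heads are initialized column by
column), which makes the single-task baseline a true architectural reduction
rather than a separate implementation.

Training minimizes the **masked MSE**: the mean of squared errors over the
(molecule, target) pairs that carry a label. Unlabelled pairs contribute
neither loss nor gradient — this is what lets one network train on
incommensurate per-target coverage. The entire forward and reverse pass is
written in vectorized base R (grouped softmax and grouped sums via `rowsum`),
and the reverse pass is verified against central finite differences in the
test suite at relative tolerance 1e-4.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `graph_feat_size` | 300 | width of atom/molecule state vectors |
| `n_attentive_layers` | 2 | message-passing rounds |
| `n_readout_timesteps` | 2 | readout refinement steps |
| `dropout` | 0.2 | dropout on the molecule embedding (training only) |
| `leakyrelu_slope` | 0.01 | LeakyReLU negative slope |
| `learning_rate` | 1e-3 | Adam step size |
| `weight_decay` | 1e-6 | L2 penalty in the Adam update |
| `batch_size` | 256 | molecules per minibatch |
| `max_epochs` / `patience` | 1000 / 20 | early-stopping budget |

The architectural and optimizer defaults are the configuration appropriate for
datasets of ~10^4 compounds. The worked examples and the test suite use a
deliberately smaller instrument — `graph_feat_size = 32`, batch 32, learning
rate 3e-3, 120–150 epochs — because they run on synthetic sets of a few
hundred molecules; these sizes are stated where used and were chosen so a full
workflow runs in minutes on one CPU core.

## Numerical choices

* **Initialization.** Glorot-uniform weights from the config seed. Two
  deliberate deviations from plain Glorot, both aimed at the long optimization
  plateau that deep recurrent message passing exhibits on small data: the
  input embedding carries a gain of 3 (one-hot atom features are sparse, and a
  stronger initial contrast between atom states lets the attention logits
  differentiate earlier), and every GRU update-gate bias starts at -1 so early
  updates favor the fresh candidate state over the carry-over.
* **Isolated atoms.** A molecule with a single heavy atom has no bonds; the
  forward pass gives such atoms a zero-bond self-loop so they receive a
  message and remain scorable. Graphs themselves store only real bonds.
* **Softmax stability.** Grouped softmaxes subtract the per-group maximum.
* **Early stopping** returns the parameter snapshot of the best monitored
  epoch, never a later one. Both the global validation R2 (the selection
  metric) and the validation loss can be monitored; the loss is the steadier
  choice early in training, when per-target R2 on small validation slices is
  noisy.
* **Divergence** (non-finite loss) aborts with a diagnostic rather than
  returning a broken model.

# Validation protocols

**Y-randomization** (`y_randomize()`): labels are permuted within each target
column, separately inside the training and validation splits, so the mask
pattern and each split's label multiset are preserved; the model is retrained
per round. A real structure-activity relationship shows a large gap between
the true model's validation R2 and every scrambled refit.

**Random hyperparameter search** (`random_search()`): uniform draws from
candidate grids (learning rate 0.1/0.01/0.001/0.0001, dropout 0.2-0.5, batch
64/128/256), each trial a full training at a reduced epoch budget, ranked by
validation R2. The learning rate is by far the most influential dial; grossly
excessive rates score markedly worse than the moderate default.

# Evaluation

Per-target R2 (`1 - SSres/SStot`), MAE and RMSE over labelled entries, with
**global** metrics defined as the *unweighted mean across targets* (sample
pooling is available as an option but is not the headline convention, because
it would let the biggest task dominate). For comparison with classification
studies, `auc_at_threshold()` binarizes the observed pIC50 at 6.0 (1 uM;
active at or below 1 uM) and computes the midrank Mann-Whitney AUC of the
continuous predictions. A gradient-boosted baseline (`gbm_baseline()`,
xgboost on 1024-bit radius-2 Morgan fingerprints) trains per target on the
identical splits as an external sanity bar.

# Atom attribution

Two routes behind one interface (`atom_weights()`):

* **Readout attention** (default): the readout's per-atom attention weights,
  averaged over timesteps. Nonnegative, summing to 1 per molecule, and
  independent of the head — they describe what the shared embedding looked at.
* **Gradient saliency**: the L2 norm per atom of the gradient of the selected
  head output(s) with respect to the final atom states; head-specific.

Weights are min-max normalized per molecule (a constant vector maps to 0.5);
**key atoms** are those with weight strictly above the molecule mean. For a
chosen substructure (SMARTS match or explicit indices),
`rank_sum_region_test()` runs the one-sided rank-sum test of the hypothesis
that region weights are stochastically greater than the rest. For molecules
with at most 12 atoms the permutation distribution of the rank-sum statistic
is enumerated exhaustively (exact even under ties); larger molecules use the
normal approximation with tie and continuity correction. Significance is
called at p < 0.05. Both normalized and raw region means are reported, since
min-max scaling changes means but never ranks (the p-value is identical on
either scale).

# Applicability domain

A distance-to-model gate on Morgan fingerprints (radius 2, 2048 bits by
default). Fitting computes each training compound's distance to its nearest
*other* training compound; `d_ave` and `theta` are the mean and standard
deviation of those distances and the threshold is \(D_T = d_{ave} + Z\theta\).
A query is inside the domain iff all of its `k` nearest training distances
are at or below \(D_T\); larger `Z` widens the domain, larger `k` tightens
it, and `ad_sweep()` tabulates the (k, Z) grid with out-of-domain counts and
partitioned metrics. Two distance kernels are provided: `1 - Tanimoto`
(default) and Euclidean distance normalized by the square root of the bit
length — both live in [0, 1] on binary fingerprints. The kernel is selectable
because "Euclidean distance on fingerprints" is reported with magnitudes in
the literature (d_ave near 0.13) that are only plausible after normalization;
when reproducing published threshold tables we use the printed `d_ave` and
`theta` as given, since the threshold arithmetic is exact regardless of how
the distances were computed.

# Chemical-space diagnostics

`pca_space()` runs PCA on 167-bit MACCS keys and reports the first three
components with a bounding-box coverage summary of validation/test chemistry
relative to training chemistry. `qed_profile()` computes Bickerton's
quantitative estimate of drug-likeness per target and the pairwise overlap
area of kernel densities on a shared 512-point grid over [0, 1].
`task_correlation()` gives pairwise-complete Pearson (or Spearman)
correlations between target pIC50 columns; Pearson is the default because the
quantity of interest is the linear exploitability of one task's labels by
another's head.

# The synthetic fixture generator

`make_fixture_dataset()` produces the desk-scale datasets used by the test
suite and the worked examples. Molecules come from a fixed grammar of
heteroaromatic scaffolds (benzene, pyridine, pyrimidine, benzimidazole,
quinoline, pyrrolopyridine, furan, thiophene cores) with two substituent
positions drawn from twenty common medicinal-chemistry groups — a pool of
roughly two thousand unique, standardizable structures. Activities follow an
additive model: `pIC50 = 5 + sum(effects of matched pharmacophores) + noise`.
Five pharmacophores (sulfonamide +2.0, piperazine +1.5, nitrile +1.0,
trifluoromethyl +0.5, amide -1.0, in pIC50 units) carry the signal; each
target's effect is a convex blend of this shared vector and a task-specific
component (fraction `shared_effect_fraction`, default 0.7), which makes
inter-task label correlation a monotone function of one dial. Gaussian noise
(sd 0.3 pIC50 units, a typical inter-laboratory IC50 spread) and per-target
label missingness (defaults 0.10/0.15/0.90/0.30 — the third task keeps only
~10% of labels, emulating the chronically under-measured family member)
complete the picture. The generator records the full pre-missingness label
matrix and the atoms of every matched pharmacophore, so multitask benefit can
be measured against noiseless-coverage ground truth and attribution can be
scored against known causal atoms.

What the fixtures deliberately do *not* emulate: activity cliffs,
scaffold-dependent (non-additive) effects, series-correlated assay error, and
the extreme chemotype redundancy of real patent-derived collections. Passing
tests on fixtures therefore demonstrate that the machinery recovers a planted
additive signal under sparsity and noise — not that real-data accuracy at
publication scale is reproduced, which would require the original
multi-database collection.

# Design decisions that were genuinely open

* **Attention inputs**: bond features are concatenated into the neighbor
  representation used for both the attention logit and the message (a switch
  at featurization level would be trivial to add; the concatenation is the
  richer default).
* **Attribution default**: readout attention rather than gradients, because
  its weights are intrinsically nonnegative, normalized per molecule, and
  task-shared — matching how atom-weight maps are usually presented; the
  gradient route is kept for head-specific questions.
* **Global metric**: mean across tasks rather than sample pooling (pooling
  available via `pool = TRUE`).
* **Duplicate rule**: minimum IC50 per (compound, target), not per compound.
* **Split rounding**: round-to-nearest for the validation/test shares,
  remainder to train.
* **Y-randomization unit**: within-column, within-split permutation —
  preserves per-task sample sizes and split-level label distributions.

# Known limitations

* Training is CPU-bound R; datasets beyond ~10^4 molecules per epoch are
  feasible but slow compared to GPU graph-learning stacks.
* The applicability domain is purely structural (fingerprint distance); it
  does not model label noise or leverage in descriptor space.
* Attribution is correlational: a significant rank-sum test says the model
  attends to a region, not that the region is causally binding-relevant.
* The chemistry backend requires a Python interpreter with RDKit on the host
  (`find_chem_python()` documents the resolution order).
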