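---
title: "Predicting protein stability changes by multiscale feature fusion"
author: "ddgfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein stability changes by multiscale feature fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddgfuse)
```

## The problem

A single amino-acid substitution changes the folding free energy of a
protein by an amount ΔΔG (kcal/mol). Predicting ΔΔG from sequence alone —
without a crystal structure — is the pre-screening step of protein
engineering: it ranks candidate mutants before anyone spends bench time on
them. Two families of sequence features carry complementary information.
*Global* features summarize how the whole sequence context shifts when one
residue changes, and are naturally extracted from protein language model
(PLM) embeddings. *Local* features describe the mutated site itself:
secondary structure, solvent accessibility, backbone geometry, disorder,
and the physicochemical identity swap. `ddgfuse` fuses the two.

A physical constraint shapes everything: thermodynamic antisymmetry. If
mutating A→B on the wild type changes stability by ΔΔG, then mutating B→A
on the mutant changes it by −ΔΔG. Good predictors should respect this;
many do not, because training sets are dominated by destabilizing
mutations in one direction.

## The model

For a wild-type sequence and its single-point mutant, the **global change
vector** is

$$ G_{pri} = \mathrm{AvgPool}(E(\mathrm{Seq}_m)) -
             \mathrm{AvgPool}(E(\mathrm{Seq}_w)), $$

where $E(\cdot)$ is a residue-level embedding matrix (L × d) from a PLM
backbone and the pooling averages over residues. $G_{pri}$ is *exactly*
antisymmetric under swapping the two sequences — by construction, not by
training — which is the structural seed of the model's learned
antisymmetry.

The **local descriptor** is the 25-vector

$$ \mathrm{Res} = [\Delta \mathrm{RSA},\ \Delta V_{\Phi\Psi},\
   \Delta \mathrm{Disorder},\ \Delta \mathrm{AAP},\
   P(SS)_w,\ P(SS)_m], $$

with $\Delta V_{\Phi\Psi}$ the difference of
$[\sin\Phi, \cos\Phi, \sin\Psi, \cos\Psi]$ encodings (removing the ±180°
periodicity artifact), ΔAAP the 13 amino-acid property changes, and the
two 3-state secondary-structure probability triples copied verbatim.
Under direction reversal the 19 difference components negate exactly and
the two triples exchange.

Each branch is encoded to 128 dimensions by two linear layers with an
H-swish nonlinearity between them,
$x \cdot \mathrm{ReLU6}(x + 3)/6$, and the branches are fused by
learnable element-wise weights:

$$ f = G \circ G_{weight} + R \circ R_{weight}. $$

(Concatenation and flattened outer-product fusion are implemented as
alternatives; linear combination is the default.) A small convolutional
decoder maps the fused vector to the scalar prediction:
two Conv1d→BatchNorm→ReLU blocks (1→16→32 channels, kernel 3, padding 1),
then flatten → Linear → BatchNorm → Linear → ŷ. The Conv→BN→ReLU and
Linear→BN→Linear orderings follow the model equations exactly.

Trained fold models are combined by arithmetic averaging into a fold
ensemble.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `d` | 32 (synthetic), 1280 (real ESM-2) | embedding width |
| `lr` | 1e-3 | Adam learning rate |
| `batch_size` | 64 | minibatch size |
| `max_epochs` / `patience` | 500 / 20 | early stopping on held-out RMSE |
| `hidden_global` / `hidden_local` | 256 / 64 | encoder hidden widths |
| `conv_channels`, `fc_hidden` | (16, 32), 64 | decoder shape |
| `fusion` | `linear_combination` | fusion mode |
| `ablation` | `full` | `wo_local` / `wo_global` zero one branch |
| `identity_threshold` | 0.25 | homology clustering threshold |

The loss (MSE), optimizer (Adam) and the decoder/encoder widths are this
package's choices — the architecture's published description fixes the
layer types and the 128-dimensional branch width but not these
hyperparameters. Fusion weights start at all-ones (a neutral fusion);
linear and convolutional layers are Xavier-uniform; every random draw
flows from one integer seed, so a fixed seed reproduces a training run
bit-for-bit on one machine.

Feature columns are rescaled to unit standard deviation before training
(stored in the model, re-applied at prediction). Columns are *not*
centered: centering would break the exact antisymmetry of the difference
features, rescaling does not.

## Providers

Embeddings and structural annotations enter through provider contracts so
the same pipeline runs with real or synthetic backends.

* `synthetic_embedder(seed, d)` — deterministic pseudo-Gaussian rows keyed
  by (seed, residue letter, position) plus a weaker whole-sequence context
  term, so a point mutation perturbs every pooled dimension slightly, the
  qualitative behaviour of a real PLM.
* `matrix_embedder(matrices)` — precomputed L × d matrices, one per
  sequence. This is the route for real ESM-2 embeddings (compute them
  externally with the `esm2_t36_650M_UR50D` checkpoint, final
  representation layer, BOS/EOS rows dropped; d = 1280). Sequences longer
  than a real backend's token limit are windowed (1000 residues centred on
  the mutation site, identically for both sequences).
* `netsurfp_annotator(csv)` — per-residue RSA, 3-state secondary-structure
  probabilities, disorder and φ/ψ in the NetSurfP-3.0 CSV dialect. Mutant
  sequences are annotated under `<protein_id>_<mutation>`; annotations for
  the mutant come from running the predictor on the full mutant sequence,
  not from copying wild-type values.
* `synthetic_annotator(seed)` — letter-dependent baselines plus
  sequence-keyed jitter; bounded, normalized, deterministic.

The 13 amino-acid properties are not fixed by the architecture; the
shipped table (`inst/extdata/aap_table.csv`) uses 13 standard published
scales (Kyte–Doolittle hydropathy, molecular weight, van der Waals
volume, Grantham polarity, isoelectric point, net charge at pH 7, H-bond
donor/acceptor counts, a flexibility index, helix and sheet propensities,
maximum ASA, aromaticity), z-normalized across the 20 residues. Any
20 × 13 table can be substituted; its version is stamped into feature
stores and checkpoints, and mismatches are errors.

## Data conventions

Positive ΔΔG is stabilizing (the ACC classifier puts exact zero on the
stabilizing side). Public datasets disagree on this sign; the CSV reader
takes `flip_sign`. Mutation codes are 1-based `A123G`. Reverse records
keep the wild-type protein id, express their code on the mutant sequence,
and inherit the fold label of their direct counterpart so a pair never
straddles a train/validation boundary. Duplicate measurements (same
protein, wild-type residue, position, mutant residue) are averaged by
`deduplicate_average()`.

Cross-validation folds respect homology: single-linkage clusters of
sequences at ≥ 25% global-alignment identity (BLOSUM62
Needleman–Wunsch) are assigned whole to the currently smallest fold,
largest cluster first. Published precomputed splits can be reproduced
exactly by supplying a `fold` column, which overrides the splitter.

## The synthetic study generator

`sim_dataset()` builds a complete desk-scale study: random sequences,
synthetic annotations and embeddings, mutations sampled uniformly, and a
*planted linear ground truth* ΔΔG = w_G·G_pri + w_R·Res + ε. The local
weights put equal-and-opposite loadings on the two P(SS) triples, so the
noiseless ΔΔG is exactly antisymmetric; direct and reverse records then
receive *independent* Gaussian noise, so a model can only achieve
antisymmetric predictions by learning the structure, not by copying.
Branch weights are rescaled so each branch contributes a configured
signal standard deviation (default 1.0 kcal/mol per branch, total ≈ 1.4,
comparable to the spread of curated stability datasets; default noise
0.3 kcal/mol).

What the generator does *not* emulate: the heavy destabilizing skew,
heteroscedastic measurement error and protein-family structure of real
thermodynamic databases, or the true nonlinear relationship between
sequence change and stability. Passing the planted-recovery tests
therefore demonstrates that the architecture, training loop and
evaluation machinery are correct and learn the statistical structure they
assume — not that the model reaches any particular accuracy on real
benchmark sets. Reproducing published benchmark numbers requires the real
650M-parameter embedding checkpoint, NetSurfP-3.0 runs for every
wild-type and mutant sequence, and full training on the curated training
set; that workflow is supported through the provider interfaces but is
not part of the test suite.

## Numerical choices

* BatchNorm: ε = 1e-5, running-statistic momentum 0.1; evaluation mode
  uses running statistics and is a pure function of (parameters, input).
  Evaluating a never-trained head is an error (there are no statistics).
* Backpropagation is hand-derived and verified against central
  differences (absolute agreement ~1e-9 in tests). Conv biases have
  exactly zero gradient through the following BatchNorm — expected, and
  left in place to keep the printed layer structure.
* Early stopping keeps the best parameters (minimum held-out RMSE, strict
  improvement 1e-8); ties keep the earlier epoch.
* P(SS) triples are renormalized on load (tolerance 1e-3); RSA and
  disorder are clamped to [0, 1]; identity-threshold ties (identity
  exactly at threshold) join the cluster.
* `sequence_identity()` returns 0 for an all-gap alignment (nothing
  aligned is nothing identical).
* Secondary-structure stratification classes come from the argmax of the
  wild-type P(SS) triple of the annotation provider, not from DSSP on
  structures (structures are deliberately out of scope); RSA strata use
  the published thresholds (buried < 0.1, exposed > 0.5).
* Ablations hard-zero the excluded branch's fused contribution, keeping
  decoder width constant so full and ablated models are directly
  comparable; zeroing the local fusion weights of a full model reproduces
  the `wo_local` model exactly (tested by parameter surgery).

## Problem sizes used in the shipped checks

Unit tests run on a memoized 8-protein / 40-variant / d = 8 study. The
planted-recovery check uses d = 32, 1000 direct + 1000 reverse records,
σ = 0.3 kcal/mol, one held-out homology fold; the ablation-ordering check
uses 400 variants; the end-to-end determinism check 125 variants with
k = 2 folds. These sizes were chosen once as realistic desk-scale
conditions and are also what `scripts/acceptance.R` re-runs.

## Known limitations

* The real-PLM path requires embeddings computed outside R; no
  GPU-side code ships with the package.
* No uncertainty estimates accompany predictions.
* The metric suite reports NA correlation for constant inputs rather than
  guessing a convention.
* Training is single-threaded base-R matrix algebra: ample for the d = 32
  synthetic studies and for fine-tuning-free heads at d = 1280, but not
  for large hyperparameter sweeps.
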