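---
title: "Methods: graph and multi-level sequence fusion for bioactivity classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph and multi-level sequence fusion for bioactivity classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `gsfl`, the design choices
that were genuinely open, the numerical conventions, and what the test
suite does and does not establish.

## The task and the data model

The package classifies small molecules as active or inactive against a
protein target from their SMILES strings. Activity is defined by potency:
IC50 values are converted to nanomolar, log10-transformed, and thresholded
at 2 (i.e. 100 nM). A value of exactly 2.0 is labeled inactive — the
threshold is a strict inequality for actives, and a conservative tie rule
keeps borderline compounds out of the positive class.

Curation (`curate_dataset`) drops multi-component records (any SMILES
containing `.`, treated as salts and removed whole rather than stripped to
the largest fragment), records without a conclusive numeric IC50, records
whose SMILES cannot be parsed, and duplicate chemical structures, detected
by Open Babel canonical SMILES with the first occurrence kept. Curation is
idempotent. Splitting (`split_dataset`) is stratified by label; validation
and test take `floor(ratio * N)` records each and the remainder goes to
training, which maximizes training data and keeps the split sizes exact and
deterministic.

## Molecular graphs

`build_mol_graph` featurizes molecules with the widely used 133/14
convention, the only standard layout matching both printed widths: one-hot
atomic number over the first 100 elements, heavy-atom degree 0–5, formal
charge (−1, −2, +1, +2, 0), chirality tag, implicit hydrogen count 0–4,
hybridization (SP…SP3D2), an aromaticity flag and atomic mass / 100 — each
one-hot block with a trailing "other" slot so exotic categories encode as a
flag rather than an error. Bonds carry a null-bond flag, bond order
(single/double/triple/aromatic), conjugation, ring membership and a
six-way stereo block. Edges are stored directed (two per bond) for message
passing, while the bond feature matrix has one row per undirected bond.

Structure perception runs through Open Babel, whose SDF export is
kekulized. Atom aromaticity is therefore taken from the SMILES notation
itself (lowercase organic-subset and bracket atoms), which is exact for the
inputs the package generates and reads; ring membership comes from
smallest-ring perception; implicit hydrogens, hybridization and conjugation
are derived with standard valence heuristics. Double-bond E/Z stereo is not
recoverable on this route, so the stereo block encodes none/any only. These
approximations affect only feature values, never matrix shapes, and carry
essentially no signal for the fixture tasks.

## Multi-level tokenization

`tokenize_smiles` scans left to right with three priorities: mined
functional-group substrings (longest pattern first, then corpus count, then
lexicographic), bracket groups `[...]` kept whole as ion-group tokens, then
single characters with `Cl`/`Br` and `%NN` ring closures kept whole.
Matching is purely textual — the decomposition operates on the SMILES
string, not the graph — with one guard: a pattern match may not end on a
`C` directly followed by `l` (or `B` before `r`), which would cut a
two-letter halogen in half. Concatenating tokens always reproduces the
input exactly; this round trip is tested over a thousand generated SMILES.

The mining step counts plain substring occurrences of a fixed candidate
family (the default patterns plus same-family carbonyl/sulfonyl/ether/ring
variants) and keeps defaults unconditionally plus any candidate reaching
`min_count`. One published default is spelled `clccccc1` in its source
table; it is treated as a typo for `c1ccccc1` since `cl` is not valid
aromatic SMILES and the accompanying decomposition example uses the
corrected form. The token dictionary reserves index 0 for padding and 1 for
unknown tokens and is otherwise sorted and deterministic.

## Graph encoder

Message passing follows a communicative scheme over directed edges. The
aggregation operator — described in prose ambiguously as a maximum pooling
of the sum combined with an element-wise product — is implemented as the
only reading consistent with all three words: the element-wise product of
the sum-pooled and max-pooled incoming edge states. Atoms with no incoming
edges receive a zero message. The edge update uses the hidden state of the
directed edge's source atom (the standard convention; the defining equation
leaves the atom unspecified). COMMUNICATE is a one-hidden-layer MLP on the
concatenated inputs, with dropout after the hidden ReLU; the final readout
additionally concatenates the raw atom features.

Feature attention is applied once, after the final readout (applying it per
layer is a configuration away but not the default): sum- and max-pooled
molecule descriptors pass through a shared bottleneck of width d/r and a
sigmoid produces per-channel weights in (0,1) that rescale every atom
vector. The reduction ratio defaults to r = 4, a conventional
squeeze-excite value; the source names the concept but no number.

Edge-state max pooling floors at zero, which is exact because edge hidden
states are ReLU outputs.

## Sequence encoder

Tokens are embedded by lookup (equivalent to one-hot times a weight matrix)
plus a learned 3-way level-tag embedding — the minimal mechanism making the
functional-group/ion/atom hierarchy visible to the flat attention that the
defining equations describe. Hierarchical attention computes
`Z = tanh(W1 X + b)`, scores `S = softmax(W2 Z)` over real positions, and
pools `h = Σ_t (X ⊙ S)`. The pooled vector broadcast back over the sequence
would, taken alone, destroy all order information, so the BiLSTM consumes
the residual combination `X ⊙ S + h` — a documented choice where the
source is silent on how the broadcast output feeds the recurrence.

The BiLSTM is a 3-layer stacked bidirectional LSTM (the "3 sequence layers"
of the selected configuration read as stack depth), 128 units per
direction, masked so padded positions carry state through unchanged. The
Transformer stage is one standard encoder block with 4 heads, feed-forward
width 4× the model width, residual connections and layer normalization,
with padded keys masked out; no positional encoding is added because order
is already injected by the recurrence.

## Fusion, head and losses

Each branch is pooled by global attention (a learned scalar gate per item,
softmax over the molecule's atoms or tokens), linearly projected to a
common fusion width (default 128; the branches' native widths 64 and 256
differ, so a shared width is required before the affine fusion
`H = W_s H_s + W_g H_g + b`, which is implemented literally as written —
affine, not gated). The head is fusion→256→64→1 with ReLU activations and
dropout after the first layer.

The training loss is `L_BCE + α·L_Contrast`, with the BCE summed (not
averaged) over the batch, as defined. The contrastive term uses
temperature-scaled cosine similarities between the L2-normalized projected
branch embeddings; the normalization target is the projected (common-width)
vectors because a cosine between the raw pooled vectors of different widths
is undefined. As printed, the denominator excludes the positive pair, so
the loss is unbounded below and can be negative — the implementation
follows the printed form by default and offers `contrastive_variant =
"ntxent"` (positive pair included, the standard bounded form) as an option.
The sum over the two modality identifiers is read as the symmetric
two-anchor form (sequence→graph and graph→sequence); otherwise it would be
a vacuous doubling. Defaults α = 0.1 and T = 0.5 are conventional values
for an auxiliary contrastive term; neither is stated by the source.

## Training, evaluation, ablations

Training uses Adam (`learning_rate` default 1e-4, `batch_size` 32, dropout
0.5 — the selected configuration), minibatches reshuffled per epoch, with
every random draw (initialization, shuffling, dropout) derived from the
configuration seed, so runs are bit-reproducible on one device. After each
epoch the model is scored on the validation split; the returned checkpoint
maximizes validation accuracy with ties broken by MCC then F1. Early
stopping waits `patience = 20` epochs (maximum 300 by default). A
non-finite loss aborts with a diagnostic rather than training on.

`compute_metrics` reports confusion counts at threshold 0.5 (no threshold
is stated by the source; 0.5 on a sigmoid output is the neutral choice)
plus ACC, SE, SP, MCC, F1, and trapezoidal areas under the ROC and
precision–recall curves swept over all distinct score thresholds. An MCC
with a zero denominator is reported as 0 with an `mcc_undefined` flag;
single-class label vectors yield NA areas. The implementation is tested to
1e-9 against an explicit threshold-loop oracle and cross-checked against
pROC.

`run_ablation` retrains five variants under identical seeds and splits:
complete; without feature attention; without hierarchical attention;
without functional-group splitting (character-level tokens only, where even
bracket groups split — deliberately crude, that is the baseline); and
graph-only, which allocates no sequence-branch parameters at all and drops
the contrastive term (there is no second modality).

## The synthetic generator

`generate_toy_dataset` assembles molecules from a fragment grammar — alkyl
chains, benzene rings, ethers and alcohols, amides, nitro groups, halogens,
stereocenters — chosen so every composition is valid SMILES and every token
family the tokenizer recognizes appears. The label is determined by
presence of an amide substructure (optionally flipped with a noise
probability), mirroring the premise that activity correlates with
functional groups and guaranteeing learnable signal in both branches.
Synthetic log-potencies are drawn at 1.0 (actives) and 3.0 (inactives) with
sd 0.3, truncated away from the 2.0 threshold so binarization is
unambiguous. The target active fraction defaults to 0.4, matching the
roughly 2:3 active:inactive imbalance of curated inhibitor sets.

The generator emulates the *structural* properties the model assumes —
parseable drug-like strings of 5–60 characters, substructure-linked labels,
class imbalance — and nothing else: real potency distributions, scaffold
diversity, activity cliffs and assay noise are all absent. Passing tests
therefore demonstrate that the machinery is wired correctly and can learn a
substructure rule, not that the architecture reaches any particular
accuracy on real inhibitor data; headline metrics on external datasets
additionally depend on dataset-specific seed and split selection that is
not reproducible from the published description and is not attempted here.

## Numerical conventions and problem sizes

Matrix layouts are row-major in the statistical sense (one row per atom,
token or molecule); batched sequence tensors are flattened time-major.
Segment softmaxes subtract a per-group maximum before exponentiation;
L2-normalization adds 1e-12 under the square root; padded slots in segment
maxima are pushed to −1e30 so they never win; masked attention adds −1e9
to excluded keys. Glorot-uniform initialization is seeded from the
configuration. Gradients of `max`-style ties go to the first argument.

The test suite runs reduced problem sizes chosen to exercise every code
path: unit oracles on 2–5 atom molecules and 3–5 token sequences, property
checks over 30–300 generated molecules, a 64-molecule noise-free
memorization run of the full architecture (learning rate 1e-3 and dropout
0.3, both from the tuning grid — a capacity check deliberately eases
regularization, since heavy dropout fights memorization by design), and
1–2-epoch ablation/CV runs at width 8 that verify structure rather than
accuracy. The memorization run stops as soon as training accuracy reaches
1.0, typically within 20 epochs.

## Known limitations

- Aromatic perception relies on the input SMILES notation; kekulized inputs
  written without lowercase notation lose the aromatic flag (the graph
  topology and all shapes are unaffected).
- Bond stereochemistry is reduced to none/any; atom parity is read from the
  SDF parity field when present.
- Functional-group mining considers a fixed candidate family, not arbitrary
  substrings, and matching is textual rather than substructure-based — two
  SMILES of the same molecule can tokenize differently.
- The autodiff engine targets this architecture; it supports the op set the
  model needs, on dense matrices, single-threaded.
- Training cost grows linearly in sequence length and batch size; the
  package is sized for datasets of hundreds to a few thousand molecules.
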