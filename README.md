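# gsfl — graph and multi-level sequence fusion learning for molecular activity

`gsfl` is an R package for binary bioactivity classification of small
molecules from SMILES strings, built around the task of recognizing BACE-1
(β-site amyloid precursor protein cleaving enzyme 1) inhibitors — a key
target in early Alzheimer's disease drug discovery. Compounds with IC50
below 100 nM (log10 IC50 in nM < 2) are labeled active.

The model fuses two complementary molecular views trained end to end:

- **Graph branch.** The molecule is a graph G = (V, E) with atom features
  X_V ∈ R^(N_V×133) and bond features X_E ∈ R^(N_E×14). After linear
  embeddings h_v⁰ = ReLU(X_V W_iV), h_e⁰ = ReLU(X_E W_iE), L rounds of
  directed-edge message passing run

      m_v = (Σ_{e∈in(v)} h_e) ⊙ (max_{e∈in(v)} h_e)
      h_v = MLP([m_v ‖ h_v]),   h_e = ReLU(h_e⁰ + W (h_src − h_e))

  followed by a readout MLP over [m_v ‖ h_v ‖ x_v]. A squeeze-excite style
  **feature attention** reweights atom channels with
  c = σ(W₁(ReLU(g_sum W₂) + ReLU(g_max W₂))), h_v′ = c ⊙ h_v, where g_sum
  and g_max pool all atoms of the molecule.

- **Sequence branch.** The SMILES string is decomposed into multi-level
  tokens — mined functional-group substrings (e.g. `C(=O)N`, `c1ccccc1`),
  bracketed ion groups kept whole (`[C@H]`, `[nH]`, `[N+]`), and remaining
  characters (with `Cl`/`Br` unsplit). Embedded tokens pass through
  **hierarchical attention** (S = softmax(W₂ tanh(W₁X + b)), pooled context
  broadcast back over the sequence), a 3-layer bidirectional LSTM
  (h_i = h_i→ ⊕ h_i←), and a Transformer self-attention block.

- **Fusion and loss.** Each branch is pooled to a molecule vector by global
  attention, projected to a common width, and fused affinely:
  H = W_s H_s + W_g H_g + b, followed by a 128→256→64→1 MLP head. Training
  minimizes L = L_BCE + α·L_Contrast, where the fusion contrastive term
  pulls each molecule's two modality embeddings together against mismatched
  pairs via temperature-scaled cosine similarities.

Because no deep-learning framework exists in base R, the package includes a
small reverse-mode automatic-differentiation engine (`R/autodiff.R`) with
fused LSTM/attention kernels; Adam, dropout, early stopping and checkpoint
selection are implemented on top of it. SMILES parsing, canonicalization and
ring perception go through ChemmineR/ChemmineOB (Open Babel). A seeded
synthetic SMILES generator (amide-substructure labels, ~2:3 class ratio)
makes every stage testable without any external download.

## Worked example

```r
library(gsfl)

# the fused tricyclic worked example: 16 heavy atoms, 18 bonds
build_mol_graph("c1(ccc2nc3CCCCc3c(c2c1)N)N")
#> mol_graph: 16 atoms x 133 features, 18 bonds x 14 features (c1(ccc2nc3CCCCc3c(c2c1)N)N)

# multi-level tokenization: functional groups > bracket groups > characters
tokenize_smiles("CC(=O)Nc1ccccc1OCC[N+](=O)[O-]", default_fg_vocab())
#> token_sequence (5 tokens): C<at> C(=O)N<fu> c1ccccc1<fu> OCC<fu> [N+](=O)[O-]<fu>

# synthetic benchmark: amide presence determines activity
d  <- generate_toy_dataset(200, seed = 1)
sp <- split_dataset(d, seed = 1)         # stratified 8:1:1
#> dataset_split (seed 1): train 160 / validation 20 / test 20

cfg <- gsfl_config(learning_rate = 1e-3, dropout = 0.3, epochs = 30,
                   patience = 10, seed = 1)
m <- train(sp, cfg)
evaluate_model(m, sp$test)
#> confusion: TP 7 FP 0 TN 13 FN 0
#> ACC 1.0000  SE 1.0000  SP 1.0000  MCC 1.0000  F1 1.0000  PRC 1.0000  AUC 1.0000
```

The fixture task is separable by construction (the label is a substructure
rule), so a correctly wired model should approach perfect test metrics; the
interesting checks are the shape contracts, the equation-level unit tests
and the ablation comparisons in `tests/testthat/`.

`run_ablation()` retrains the five architecture variants (complete model,
−feature attention, −hierarchical attention, −functional-group splitting,
graph-only) under identical seeds and returns a seven-metric table;
`cross_validate()` runs stratified k-fold CV and `run_seeds()` repeats the
whole experiment over seeds, reporting mean ± SD.

A thin command-line wrapper ships in `inst/cli/gsfl`
(`make-fixtures`, `featurize`, `tokenize`, `train`, `evaluate`, `cv`,
`ablate`).

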