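# ddifuse

Multi-view feature fusion for drug–drug interaction (DDI) prediction in R.

Co-administered drugs can interact, sometimes harmfully, and screening every
candidate pair experimentally is infeasible. `ddifuse` treats DDI prediction
as binary classification over drug pairs, `f(d_i, d_j) ∈ [0, 1]`, and encodes
each drug from three complementary views of its SMILES string:

1. **Sequence channel** — the SMILES is decomposed into
   frequent-consecutive-subsequence (FCS) tokens — medium-sized substructures
   mined by greedy adjacent-pair merging — and encoded by a transformer
   (8 heads), pooled by a PAD-masked mean to a 75-dimensional vector
   `f_seq`.
2. **Graph channel** — a message-passing attention network on the 2D
   molecular graph: attention-weighted neighbor messages, GRU node updates
   (`h_v^{k+1} = GRU(m_v^k, h_v^k)`, K = 2 rounds, 25-dimensional messages),
   and a self-attention graph-pooling readout over `(h_v^K, h_v^0)` giving
   `f_graph` (length 75).
3. **Spatial-semantic channel** — atoms carry nine categorical features plus
   degree-based centrality embeddings; every atom pair adds an attention
   bias combining a learned shortest-path-distance embedding (with a
   reserved bucket for disconnected pairs, `s(x,y) = −1`) and the mean bond
   embedding along one deterministic shortest path. Three ProbSparse
   self-attention blocks (8 heads, hidden 256) produce `f_semantic`.

A softmax attention gate fuses the views per drug,
`F_d = α_s f_seq + α_g f_graph + α_sem f_semantic` with `Σα = 1`, and a
Siamese three-layer decoder with a final sigmoid scores each pair; training
minimizes binary cross-entropy with Adam (lr 1e-4, batch 16), on random
8:1:1 splits with repeated-run averaging, channel ablations, and robustness
subsampling.

There is no deep-learning framework dependency: forward and backward passes
run on a reverse-mode autodiff tape written in R with C++ (RcppArmadillo)
kernels for attention, transformer blocks and the Adam update. Molecular
parsing and atom/bond properties come from RDKit via the system `python`.

## Worked example

The package ships a synthetic benchmark generator that builds valid toy
molecules from a motif grammar and labels pairs by a planted, symmetric
substructure rule (by default: one drug carries a carboxyl group, the other
an amine), with balanced negatives:

```r
library(ddifuse)

ds  <- synthetic_dataset(n_drugs = 80, n_pairs = 300, seed = 7)
cfg <- model_config(train = list(epochs = 5, seed = 7))
sp  <- split_dataset(ds$pairs, seed = 7)
fit <- fit_ddi(ds$drugs, sp$train, sp$valid, config = cfg)

glance(fit)
#> # A tibble: 1 × 5
#>   epochs best_epoch train_loss_final valid_auroc_best n_parameters
#>    <int>      <int>            <dbl>            <dbl>        <int>
#> 1      5          3            0.145            0.973      1493469

evaluate_ddi(fit, sp$test)
#> # A tibble: 1 × 4
#>     acc auroc    f1     n
#>   <dbl> <dbl> <dbl> <int>
#> 1 0.933     1 0.929    30

head(predict(fit, sp$test), 4)
#> # A tibble: 4 × 5
#>   drug_id_1 drug_id_2 label probability predicted_label
#>   <chr>     <chr>     <int>       <dbl>           <int>
#> 1 D0027     D0039         0      0.0235               0
#> 2 D0003     D0022         0      0.0573               0
#> 3 D0037     D0050         0      0.0686               0
#> 4 D0036     D0047         1      0.811                1
```

After five epochs on 240 training pairs the model ranks every held-out test
pair correctly (AUROC 1) and classifies 93% at the 0.5 threshold; the
probabilities separate interacting pairs (≈ 0.8) from non-interacting ones
(≈ 0.02–0.07). `autoplot(fit)` draws the loss and validation curves;
`tidy(fit)` returns them as a long tibble. `ablate()` runs the seven
channel-toggle variants (`full`, `no_seq`, `no_graph`, `no_semantic`,
`seq_only`, `graph_only`, `semantic_only`) under one seed and split.

Real datasets are plain delimited tables — `drug_id,smiles` and
`drug_id_1,drug_id_2,label` — read with `read_drug_table()` /
`read_pair_table()`. A thin command-line wrapper is installed at
`exec/ddifuse` with subcommands `build-vocab`, `simulate`, `train`,
`evaluate`, `predict` and `ablate`.

## Documentation

The methods vignette (`vignettes/ddifuse-methods.Rmd`) describes the model,
its assumptions, every tunable parameter with units and defaults, the
numerical conventions for degenerate inputs, what the synthetic benchmark
does and does not demonstrate, and known limitations.
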