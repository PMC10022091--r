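# dualsyn

Predicting whether a drug pair acts **synergistically or antagonistically**
in a cancer cell line, from three inputs per observation: the SMILES strings
of the two drugs, their hashed atom-pair fingerprints, and the
gene-expression profile of the cell line.

`dualsyn` is an R implementation of a dual-feature-fusion neural
architecture for binary synergy classification, built for method study and
benchmarking at desk scale. It is aimed at computational chemists and
bioinformaticians who want a fully inspectable, dependency-light
implementation of the architecture's mechanisms — contrastive SMILES
encoding, two-view feature fusion, R-drop regularization, leakage-audited
cross-validation — that can be exercised end-to-end on seeded synthetic
data without GPU training or external downloads.

## The model

For a record (drug *A*, drug *B*, cell line *c*):

1. **SMILES encoder.** A small from-scratch transformer over SMILES tokens
   produces embeddings *x_A*, *x_B*. It is fine-tuned with the SimCSE
   contrastive objective: the same string is encoded twice under
   independent dropout masks, giving views *h_i*, *h_i′*; the loss for a
   batch of *N* pairs is

       ℓ_i = −log [ exp(sim(h_i, h_i′)/τ) / Σ_j exp(sim(h_i, h_j′)/τ) ]

   with cosine similarity and temperature τ (default 0.05).
2. **Featurization.** Each drug also gets a hashed atom-pair fingerprint
   *f_A*, *f_B* (atom-pair descriptor codes folded modulo `nBits`,
   default 2048); the cell line contributes its expression vector *z*.
3. **Dimensional alignment.** Affine maps g(x) = Wx + b project all five
   inputs to one dimension *d*, giving the fusion input
   l = concat(f_A′, f_B′, z′, x_A′, x_B′).
4. **Dual fusion.** Two parallel views of the same numbers:
   - *vector level*: l as a 5-token sequence through multi-head
     scaled-dot-product attention, plus a projected residual l·W^R,
     then ReLU → m_vec;
   - *bit level*: l as a flat 5d vector through a highway network,
     m_bit = g ⊙ t(l) + (1−g) ⊙ q(l), with sigmoid gate g = σ(l), ReLU
     transform t and linear carry q.
5. **Head and loss.** m_x = m_vec + m_bit → LayerNorm → linear → sigmoid
   gives the synergy probability ŷ. Training passes every batch through
   the network **twice** (independent dropout) and minimizes

       L = ½(CE(ŷ₁, y) + CE(ŷ₂, y)) + α · ½(KL(ŷ₁‖ŷ₂) + KL(ŷ₂‖ŷ₁))

   (R-drop). Evaluation reports ACC, BACC, Prec, Rec, F1, ROC-AUC, MCC,
   Cohen's kappa and AP, with splits that are audited to hold out whole
   drug pairs, drugs, or cell lines.

All gradients are computed by a small reverse-mode autodiff included in the
package and verified against finite differences in the test suite.

## Worked example

```r
library(dualsyn)

# seeded synthetic corpus with a planted, learnable synergy rule
exp <- generateSynergyDataset(nDrugs = 25, nCellLines = 10, nGenes = 100,
                              nRecords = 2000, ratio = 0.4,
                              labelNoise = 0.05, seed = 7)
exp
#> SynergyExperiment with 2000 records
#>   drugs: 25  cell lines: 10  genes: 100
#>   synergistic:antagonistic = 611 : 1389

plan <- stratifiedKfold(exp, k = 5, seed = 42)
f <- folds(plan)[[1]]

enc <- smilesEncoder(encoderConfig(dim = 64, layers = 2, heads = 4, seed = 7))
ft  <- finetuneEncoder(enc, drugLibrary(exp), epochs = 3, batchSize = 16, seed = 7)

cfg   <- trainConfig(d = 32, heads = 2, epochs = 20, batchSize = 32,
                     dropout = 0.1, alpha = 1, seed = 7)
model <- trainSynergyModel(exp, ft$encoder, cfg, trainIdx = f$train)
evaluateModel(model, exp, idx = f$test)
#> MetricReport (TP=93 TN=250 FP=28 FN=30)
#>     ACC    BACC    Prec     Rec      F1 ROC_AUC     MCC   Kappa      AP
#>  0.8554  0.8277  0.7686  0.7561  0.7623  0.9055  0.6584  0.6584  0.8498
```

The held-out ROC-AUC of ~0.91 reflects recovery of the planted rule
(fingerprint-similarity plus cell-line signal, 5% label noise); a
label-permuted control under the same settings stays near 0.5, and ablating
the fingerprint input costs more AUC than ablating any other single input.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/dualsyn.R simulate --out data --seed 5 --n-records 200
Rscript inst/cli/dualsyn.R split    --dataset data/dataset.csv --scheme stratified --k 5 --seed 5 --out plan.json
Rscript inst/cli/dualsyn.R train    --dataset data/dataset.csv --expression data/expression.csv \
                                    --out run --seed 5 --plan plan.json --fold 1
Rscript inst/cli/dualsyn.R evaluate --model run/model.rds --dataset data/dataset.csv \
                                    --expression data/expression.csv --plan plan.json --fold 1 --out metrics.json
```

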