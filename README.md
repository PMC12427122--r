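# mkdr

Multi-omics drug response prediction with missing-modality completion and
teacher–student knowledge distillation, in pure R.

## The problem

Drug response prediction (DRP) estimates how sensitive a cancer cell line is
to a compound — its IC50 — from molecular profiles: gene expression (GE),
copy number variation (CNV) and mutation status (MU), together with the
drug's structure (SMILES). Real multi-omics panels are incomplete: many
samples lack one or more modalities, and models that assume complete inputs
degrade sharply when a layer is missing. `mkdr` addresses this with two
coupled ideas:

- **Modality completion.** A variational autoencoder learns
  `z ~ q(z | x_GE)` on complete samples and reconstructs CNV (Gaussian
  likelihood) and MU (Bernoulli likelihood) from gene expression, so a
  GE-only sample can still present three modalities to the predictor.
- **Knowledge distillation.** A *teacher* network trained on
  complete-modality samples supervises a *student* that sees GE plus
  completed CNV/MU, through the loss
  `L = α·(ŷ_s − y)² + (1 − α)·KL(P_t ‖ P_s)`, where predictions are treated
  as Gaussians with variance T² so the divergence is
  `(ŷ_t − ŷ_s)²/(2T²)` and T is a softening temperature.

The shared network is: per-modality self-attention encoders over grouped
feature tokens (`softmax(QKᵀ/√d)V`), a bi-directional LSTM over tokenized
SMILES, cross-modal attention fusion with the drug as query and the omics
tokens as keys/values, and a sigmoid-bounded regression head for the
(log-transformed, IQR-filtered, min–max scaled) response. Integrated
gradients provide per-feature attributions, modality-level contribution
shares and top-k feature rankings.

A seeded synthetic generator reproduces the statistical structure the method
assumes — a shared low-dimensional cell state drives all three omics layers,
drug identity is decodable from token composition, and the response is a
bilinear-plus-quadratic cell×drug interaction — so the entire pipeline is
testable on one CPU without external data.

## Worked example

```r
library(mkdr)

# synthetic multi-omics panel: 60 cell lines x 40 drugs, default conditions
sim    <- simulate_mkdr(sim_config(seed = 1))
resp   <- make_split(preprocess_responses(sim$responses_raw), seed = 102)
bundle <- list(omics = sim$omics, drugs = sim$drugs, responses = resp)

# complete CNV/MU from gene expression
completer <- fit_vae(bundle$omics, vae_config(seed = 1), holdout_fraction = 0.2)
print(completer$holdout_report)

# teacher on complete modalities, student on completed ones
cfg     <- encoder_config(d_model = 16, n_heads = 2, n_layers = 1, n_tokens = 8,
                          head_hidden = 16)
teacher <- train_teacher(bundle, cfg = cfg, epochs = 250, lr = 5e-3, seed = 1)
student <- train_student(bundle, teacher = teacher, completer = completer,
                         kd = kd_config(alpha = 0.5, temperature = 1),
                         epochs = 250, lr = 5e-3, seed = 1)
print(evaluate_model(student, bundle, "test", completer = completer))

# where does the student look? integrated-gradients modality shares
pairs <- resp[resp$split == "test", c("cell_id", "drug_id")][1:6, ]
aset  <- attribute_set(student, bundle, pairs, steps = 64, completer = completer)
round(modality_shares(aset), 1)
```

Output from this exact session:

```
Completion report over 12 cells
 cnv_pcc_mean   cnv_r2_mean  cnv_mse_mean  cnv_mae_mean mu_auroc_mean
       0.9183        0.7993        0.1991        0.3392        0.8865
  MU features with undefined AUROC: 10 of 80

Drug response metrics (n = 231)
   MSE   RMSE    MAE     R2    PCC    SCC
0.0209 0.1445 0.1115 0.4105 0.6620 0.6403

  ge  cnv   mu
64.3 19.9 15.8
```

The completion report says the VAE reconstructs held-out CNV profiles with
mean per-feature Pearson correlation 0.92 and separates mutation carriers
with mean AUROC 0.89 — the cross-modal dependence planted by the generator
(features whose held-out cells are all one class have no defined AUROC and
are flagged). The student's test metrics are on the scaled `[0, 1]`
response (`inverse_response()` maps predictions back to concentrations).
The shares show the student spreading its attributions across all three
modalities even though its CNV/MU inputs were synthesised from GE — the
structural signature of effective completion plus distillation.

The same pipeline is scriptable end-to-end with caching and a manifest:

```r
run_pipeline(list(student = list(variant = "full")), out = "run1", seed = 1)
```

or from the shell via the thin CLI at `inst/cli/mkdr`
(`mkdr pipeline --seed 1 --out run1`, plus per-stage subcommands
`simulate`, `train-vae`, `train-teacher`, `train-student`, `evaluate`,
`ablate`, `attribute`).

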