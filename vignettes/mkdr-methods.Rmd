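---
title: "Modality completion and knowledge distillation for drug response prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modality completion and knowledge distillation for drug response prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Predicting the sensitivity of a cancer cell line to a drug (its IC50) from
molecular profiles is a standard regression task in pharmacogenomics. Multi-
omics models combine gene expression (GE), copy number variation (CNV) and
mutation status (MU), but real panels are incomplete: many samples lack one
or more modalities, and the missingness is usually informative. `mkdr`
implements a framework that stays usable under such missingness by

1. **completing** absent CNV/MU profiles from gene expression with a
   variational autoencoder (VAE), and
2. **distilling** a teacher network trained on complete-modality samples
   into a student network that sees only gene expression plus completed
   modalities.

Everything runs at desk scale on synthetic data with the statistical
structure the method assumes, so every stage is testable without external
downloads.

# The network

## Omics encoders

Each modality's feature vector is partitioned into `n_tokens` contiguous
groups; each group is linearly embedded to `d_model` dimensions and receives
a learned positional embedding. The resulting token sequence passes through
`n_layers` blocks of multi-head self-attention plus a position-wise
feed-forward layer, both with residual connections. Attention is the scaled
dot product

$$\mathrm{Attention}(Q, K, V) = \mathrm{softmax}\!\left(\frac{QK^\top}{\sqrt{d}}\right)V,$$

with the conventional $1/\sqrt{d}$ scaling (the literature sometimes prints
the scale ambiguously; the square-root form is the numerically standard
choice and is what `attention()` implements). Token grouping is the simplest
reading of "self-attention over an omics vector" that keeps attention
meaningful: per-gene tokens are infeasible at realistic feature counts, and
a single token degenerates to an MLP. The group count is a tunable
(`encoder_config(n_tokens = )`, default 16).

We deliberately omit layer normalisation: at the widths used here (tens of
dimensions) training is stable with Adam and residual connections alone, and
the omission keeps the backward pass simple and exactly reproducible.

## Drug encoder

SMILES strings are tokenized at atom level (bracket atoms, two-letter
halogens, ring digits and bond symbols are single tokens), embedded, and run
through a bi-directional LSTM. The drug representation pools the per-position
hidden states over non-PAD positions; mean pooling is the default, the last
hidden state is available (`pool = "last"`). Both appear in the literature;
mean pooling is less sensitive to sequence length. The representation is
invariant to trailing padding by construction (masked pooling; the reverse
direction reads each sequence reversed within its true length).

## Fusion and head

The drug representation queries the concatenated omics token matrices
(keys = values), yielding a fused vector $Z$; a residual connection from the
drug representation is added by default (`residual = FALSE` recovers the
plain attention equation) so an uninformative omics context cannot erase
drug identity. A two-layer MLP with a sigmoid output maps $Z$ to a predicted
response in $(0, 1)$, matching the scaled target. The fusion attention
weights are retained for interpretability.

## Teacher and student

Both roles share the identical architecture; only inputs differ. The teacher
consumes observed CNV/MU (it refuses unobserved modalities unless a
completer is supplied). The student always routes CNV/MU through the
completion path — even for cells where they were observed — so its inputs
are well-defined under any missingness pattern and its attributions can be
read on the completed representation; `use_observed = TRUE` exposes the
mixed mode.

# Modality completion

The VAE encodes GE into a Gaussian posterior $q_\phi(z \mid x_{ge})$
(tanh hidden layer, default width 64, latent dimension 16) and decodes CNV
with a Gaussian likelihood (squared error) and MU with a Bernoulli
likelihood (cross-entropy). Training minimises the negative evidence lower
bound: reconstruction NLL plus $\beta \cdot KL(q_\phi \| \mathcal N(0, I))$
in closed form, with reparameterised sampling. Mutation data is binary, so
a Gaussian likelihood there would be wrong — the likelihood split is forced
by the data types even though completion losses are often written
generically.

Inference uses the posterior mean, never a sample: downstream predictions
and attributions must be deterministic; `complete(..., sample = TRUE)`
retains the stochastic mode. Training uses decoupled (AdamW-style) weight
decay (default `1e-2`), which matters at the small sample sizes the desk
scale implies (tens of complete cells against hundreds of decoder outputs).
The default 500 epochs sits before the overfitting regime we observe on the
synthetic panels; the KL weight is 1 with an optional linear annealing ramp.

# Knowledge distillation

The student minimises

$$L = \alpha \, (\hat y_s - y)^2 + (1 - \alpha)\, KL(P_t \,\|\, P_s).$$

Predictions are scalars, so the divergence needs a distributional reading:
we model both predictions as Gaussians with common variance $T^2$, giving
$KL = (\hat y_t - \hat y_s)^2 / (2T^2)$ — the temperature is then a genuine
softening knob that scales the distillation gradient. A binned alternative
(discretise $[0,1]$ into `n_bins`, softmax of negative squared distances at
temperature $T$, standard KD divergence) is available via
`kd_config(kl_mode = "binned")` for sensitivity analysis. Defaults:
$\alpha = 0.5$, $T = 1$. At $\alpha = 1$ the objective reduces to the task
loss exactly, by construction, for any $T$.

Teacher targets are computed on the teacher's own view of each training
pair: true CNV/MU where the cell is complete, completed otherwise. The
teacher's parameters are never updated during student training.

Ablation variants follow the usual naming: `full` (completion +
distillation), `nk` (completion only, $\alpha$ forced to 1), `nm`
(distillation with training-mean fill instead of completion), `nkm`
(neither). Mean fill is the no-completion baseline; zero fill is a flag.
Feature compression keeps the top `ceiling(f * n)` features per modality by
training-cell variance — variance ranking is the simplest defensible
criterion and is pluggable.

# Response preprocessing

IC50 concentrations are log-transformed (natural log by default; the base is
a knob because min–max scaling makes it immaterial), outliers are excluded
by the IQR fence rule $[Q_1 - k\,\mathrm{IQR},\, Q_3 + k\,\mathrm{IQR}]$
with $k = 1.5$ and linear-interpolation quantiles (`type = 7`), and the
surviving log values are min–max scaled to $[0, 1]$. Fences and scaling
constants are frozen with the table, making the exclusion reproducible and
the transform invertible. Fences are global by default; per-drug fences are
a flag.

Scaling is computed on all IQR-kept rows by default. Computing it on the
training split alone avoids a (trivial) leak of the target range but pushes
validation/test responses outside $[0, 1]$, breaking the contract that the
sigmoid-bounded head can represent every target; `make_split(...,
rescale_on_train = TRUE)` provides the strict variant.

Splits are stratified by drug: each drug's rows are allocated to
train/val/test by largest remainder, so per-drug proportions deviate from
the global 80/10/10 by at most one row. Training subsets (1/16 … 1/2)
relabel training rows only; validation and test sets are frozen.

# The synthetic data generator

A shared latent state $H \in \mathbb R^{n_{cells} \times k}$ drives all
three omics layers: GE and CNV are noisy linear maps of $H$, MU is Bernoulli
with logits linear in $H$ and an intercept calibrated by root-finding so the
mean mutation rate hits its target. This makes CNV and MU recoverable from
GE through the latent — exactly the dependence the completer must learn.
Mutation loadings are drawn at $\mathrm{sd} = 4/\sqrt k$, chosen so the
latent separates carriers strongly (Bayes-level AUROC ≈ 0.95); weaker
loadings leave even the optimal predictor below the discriminability the
completion analysis assumes.

Drugs are token sequences over a fixed SMILES-like alphabet (not chemically
valid molecules — the encoder consumes tokens, so validity is irrelevant to
testing); the drug latent is a fixed random projection of the token-count
vector, so the sequence encoder can learn it. The noiseless response is a
bilinear cell-by-drug interaction plus a mild quadratic term (so fusion has
nonlinearity to exploit), standardised and squashed through a logistic into
$(0, 1)$; observed IC50 is $\exp(\text{scale} \cdot f + \varepsilon)$.
Missingness removes whole (sample, modality) blocks at a configured
Bernoulli rate, flagged in an explicit mask — never sentinel values.

Defaults — 60 cells, 40 drugs, 200/60/80 GE/CNV/MU features, $k = 8$,
observation noise 0.05, response noise 0.1, mutation rate 0.15 — preserve
the GE ≫ CNV/MU dimensional ordering of real panels at a size that trains in
minutes on one CPU.

What the generator does **not** emulate: copy-number segment structure, gene
networks, linkage, realistic chemistry, and modality-specific response
information. That last point matters for interpreting results: because every
modality flows from the same latent and the completer conditions only on GE,
completion adds representation, not information. Gains of the completed-and-
distilled student over mean-fill baselines on this data are therefore
regularisation/representation effects — the same mechanism the full-scale
method invokes — and they are correspondingly modest (a majority-of-seeds
ordering, not a large gap). Passing tests show the machinery is correct and
the orderings hold; they do not certify effect sizes on real panels.

# Numerical choices

- **Automatic differentiation.** No deep-learning framework is available to
  R here, so the package carries a small reverse-mode tape on numeric
  arrays (`R/autodiff.R`) with hand-derived backward passes for batched
  attention; all gradients are finite-difference-verified in development.
  Optimisation is Adam with optional decoupled weight decay.
- **Determinism.** Every source of randomness is seeded through R's RNG and
  each entry point swaps the RNG state in and restores it on exit. Training
  is full-batch; predictions are row-independent, so results are invariant
  to batch composition. Same seed ⇒ bit-identical parameters, metrics and
  reports.
- **Integrated gradients** use the left-Riemann path integral with the
  baseline defaulting to the per-feature training-view mean (a zero
  baseline is wrong for standardised omics); 128 steps by default. The
  completeness residual is reported with every attribution. Student
  attributions are computed against the completed three-modality view by
  default (`mode = "completed"`); `mode = "ge_only"` differentiates end-to-
  end through the completer and attributes raw GE only. Drug tokens are
  attributed on the same path at the embedding level against a zero
  embedding and reported separately from the omics shares.
- **Spearman ties** use average ranks; **R²** uses the evaluation-set mean
  for the total sum of squares; AUROC per mutation feature requires both
  classes, otherwise it is flagged undefined.
- **Degenerate inputs** are hard errors with informative messages:
  non-positive IC50, zero response range, non-binary mutation entries
  (named cell), duplicate sample/drug ids, all-PAD token sequences,
  unobserved modalities without a completion path.

# Problem sizes in tests and the acceptance script

The packaged analyses run the default generator conditions with a compact
encoder (`d_model = 16`, 2 heads, 1 layer, 8 tokens per modality, 250
training epochs with early stopping) — our standard desk-scale analysis
configuration; the wider defaults of `encoder_config()` are the
documented starting point for larger data. Multi-seed comparisons
(completion vs mean imputation; full student vs bare variant at 40%
missingness and quarter training data; error versus training-set size) use
five seeds each, mirroring the seed-wise design of the underlying study.

# Limitations

- The scalar-regression reading of the distillation divergence is one of
  several; the binned variant is provided but not the default.
- The completer conditions on GE only. Conditioning on arbitrary observed
  subsets is a natural extension and is deliberately out of scope.
- Desk-scale results quantify orderings and learnability, not absolute
  performance on CCLE/PRISM-scale panels; no claim in this package depends
  on reproducing published absolute metric values.
- The per-drug metric table requires at least three pairs per drug; drugs
  below the threshold are listed with a reason rather than reported.
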