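---
title: "Modeling cis-regulation with hierarchical attention: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cis-regulation with hierarchical attention: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Which candidate cis-regulatory elements (cCREs) drive a gene's
expression? Perturbation screens answer this for a handful of loci;
`attnreg` takes the modeling route: train a network to predict a gene's
expression from the DNA sequence and chromatin signal (DNase, histone
and TF ChIP) of the cCREs flanking its TSS, then read candidate
enhancer–gene interactions *zero-shot* out of the trained model's
attention weights — the model is never shown an interaction label.

# Model

The architecture is hierarchical, with two transformer encoders.

**Element encoder.** Each cCRE is padded (or centre-cropped) to a fixed
350 bp. Every base is embedded as the sum of a DNA embedding (linear
projection of the one-hot sequence, code order `A, T, C, G, N`) and a
signal embedding (linear projection of the per-base track vector), into
`d_model` channels. A learnable `[CLS]` token is prepended, and a
2-layer, 4-head transformer encoder lets it attend the bases; its
output is the element representation. Attention uses scaled dot
products with an additive, learned relative-position bias in the T5
style: the signed base offset is bucketed (exact buckets for small
offsets, log-spaced to a 128-bp saturation), and each head in each
layer learns one scalar per bucket. Feed-forward sublayers are
`max(xW1 + b1, 0) W2 + b2` with `d_ff = 4 d_model`.

**Regulation encoder.** For one gene, the context is the up-to-200
nearest elements on each side of the TSS (optionally restricted to a
±1 Mb candidate window). Tokens are a shared learnable `[GENE]`
embedding plus the element representations; genes are distinguished
only by their TSS coordinate. A 4-layer, 4-head transformer with the
same relative-bias mechanism — buckets now over signed genomic
distances, saturating at 1 Mb — models gene–element and
element–element interactions. The gene token's output passes through a
linear projection and a softplus, yielding a strictly positive
predicted expression rate trained under a Poisson negative
log-likelihood, `mean(lambda - y log lambda)`.

**Masking.** Attention between distinct gene tokens is blocked (logits
set to `-Inf`, so their softmax weight is exactly 0); a gene token may
attend itself and all elements. We additionally block element-to-gene
attention in the model's forward pass, making gene tokens pure readout
queries. This is a design choice the minimal mask does not force: with
it, element representations are independent of which genes share the
context, so a multi-gene window is *exactly* equivalent to running each
gene alone — the property the masking is meant to guarantee — and
nothing is lost, because gene tokens carry no genomic content that
elements could usefully read back. `build_gene_gene_mask()` exposes
both variants.

**Positional design.** All coordinates are 0-based half-open (BED
convention). The element–gene distance anchor is the element interval's
midpoint, which is invariant under the symmetric padding. Distances are
signed; strand is recorded but not used. Log-distance terms are floored
at 11 bp (`log10(11) ≈ 1.04`) so that division by `log10(d)` never
blows up near a TSS; the same floor is used by the generator, the
attention adjustment and the ABC-style baseline.

# Training

AdamW (betas 0.9/0.999, decoupled weight decay 0.01 — standard values,
all in the config) with the reference schedule: batch size 8, 50,000
steps, learning rate warmed linearly from 0 to 1e-3 over the first
5,000 steps and decayed linearly to 1e-8; gradient L2 norm clipped at
1.0; dropout 0.1. The desk preset scales steps and warmup by the same
ratio (2,000 / 200) so the schedule's shape is preserved. Training
targets default to log1p expression — matching how RNA-seq targets are
preprocessed (sum of transcript TPM, then log1p) — treated as a
count-like value under the Poisson loss; a config switch trains
against raw counts where they exist (synthetic data). Validation uses
the Pearson r between observed and predicted values; the best
validation checkpoint is kept. All randomness (initialisation,
shuffling, dropout) flows from one seed, and equal seeds reproduce
loss trajectories exactly on CPU.

**Two-stage desk mode.** The backward pass is implemented end to end —
gradients flow through the regulation encoder into every element
encoder parameter, verified against finite differences — and joint
training is the default configuration. The desk preset instead freezes
the element encoder at its seeded random initialisation, precomputes
all element embeddings once, and trains only the regulation encoder
and head. Re-encoding a few hundred 350-bp elements at every step
costs roughly two orders of magnitude more than the regulation
encoder itself; random transformer features preserve the per-element
signal content almost losslessly (a linear probe recovers the summed
H3K27ac and DNase of an element from its frozen embedding with
R² > 0.95), so the desk-scale conclusions do not depend on element
fine-tuning. Joint training remains exercised at micro scale in the
test suite.

# Interpreting attention

Attention logits and weights are retained per layer and head. The
default interaction score for a (gene, element) pair is the arithmetic
mean of the softmax attention over all layers and heads of the gene
query row at the element's key column — the combination rule across
layers/heads is a package choice (a `max` reducer and per-layer
restriction are available). Scores are then normalised per gene:
min-max to [0, 1] (a constant row maps to 0.5, with a warning) or
softmax. The distance-adjusted score divides by `log10(distance)`,
which consistently improves ranking because attention alone
under-penalises distal decoys.

Element–element attention aggregates into square matrices at 10-kb
resolution (min-max normalised over the matrix, summed per bin pair,
symmetrised by averaging with the transpose), comparable side by side
with contact matrices binned from pair records under the same
convention. The insulation score of a boundary bin `b` (boundary
between bins `b` and `b+1`) is the sum of the 3×3 window
`rows b-2..b × cols b+1..b+3` — one bin off the diagonal, spanning the
last three upstream and first three downstream bins. On a noiseless
two-block matrix (within 2, between 0) it is exactly 0 at the planted
boundary and 18 deep inside a block, and — because the window lies
fully across the boundary at exactly one bin — the boundary-centred
profile has an unambiguous strict minimum at offset 0. (A window that
excludes bin `b` from both sides straddles the boundary at two
adjacent offsets, which under noise turns the location of the minimum
into a coin flip between them; that is why the window includes the
last upstream bin.) Averaged over boundaries and
offsets it produces the boundary-centred insulation curve; the same
convention is applied to attention and contact matrices so their
comparison is internally consistent. CTCF-bound element pairs are
grouped by topology (same boundary, flanking TAD, adjacent or remote
boundaries) on *unnormalised* mean attention; directional region-level
scores compare mean attention A→B vs B→A, with a Mann–Whitney U test
against matched-distance element pairs from other genes' contexts
(tolerance: 20% of the distance plus 5 kb) when a background is
supplied, and no p-value otherwise.

# Benchmarks

Pair labels come either from planted ground truth (synthetic data),
from screened-element universes ("gene-mapped negatives": every
screened element within a closed 1-Mb window of a positive gene's TSS,
non-positives labelled 0), or from interaction records (positive iff
one anchor overlaps the gene body and the other the element, either
order). Baselines: `1/distance`, and an Activity-by-Contact style
score `sqrt(H3K27ac_sum * DNase_sum) / distance`. Metrics: auROC
(rank-based, tie-averaged) and auPRC (step-wise average precision),
checked in the tests against exhaustive pair-counting and
step-integration oracles; distance strata are the half-open groups
0–5 kb, 5–50 kb, 50–1000 kb, 1000 kb+, with strata under 10 pairs or
with a single label class dropped. Precision and specificity use the
mean score as the classification cutoff.

# The synthetic generator

`simulate_genome()` plants a fully known regulatory landscape on one
chromosome: non-overlapping elements with LogNormal(0, 1) activities
`a_e`; per-element effects `w_e ~ LogNormal(0, 0.5)`; each gene draws
`regulators_per_gene` elements within `max_link_distance` of its TSS
with probability ∝ `1/log10(max(|d|, 11))`; the expression rate is

```
mu_g = baseline_rate + effect_scale * sum_e  w_e * a_e / log10(max(|d_ge|, 11))
```

with `y_g ~ Poisson(mu_g)` observed and stored as `log1p(y_g)` (raw
counts kept). Signals are unimodal per-base bumps plus truncated
Gaussian noise: DNase scales with `a_e`; H3K27ac with `w_e` for
regulators and 0 otherwise; CTCF is high only for TAD-boundary
elements; remaining tracks are pure noise. Regulators carry an 8-mer
motif at their centre. TSSs are placed quasi-evenly (stratified with
jitter). Block contact matrices with planted boundaries complete the
insulation fixtures. What the generator does *not* emulate: motif
grammar and TF cooperativity, nucleosome structure, multi-chromosome
genomes, cell-type mixtures, replication timing or mapping artefacts —
so passing recovery tests demonstrates that the architecture and
training recover the planted generative structure, not that the model
generalises to real chromatin.

## Desk-scale study conditions and identifiability

The desk recovery experiment (`sim_config_desk()`,
`run_recovery_experiment()`) uses 200 genes tiling a 100-Mb
chromosome, 1,200 elements, ±250-kb candidate windows (~6 elements
each), 4 regulators per gene, `effect_scale = 15` against
`baseline_rate = 4`, `noise_sd = 0.3`, trained at `d_model = 64` for
2,000 steps. Two properties of these conditions matter and were chosen
by analysis, not by tuning on outcomes:

* **Held-out predictability.** Regulator membership is a latent draw.
  With many near-equivalent candidates per window, most expression
  variance sits in which candidates happened to be drawn — a quantity
  no model can infer for an unseen gene. A marginalised-membership
  oracle (exact inclusion probabilities, true signal sums) caps
  held-out r near 0.3 when windows hold ~40 candidates, and near 0.8
  at ~6 candidates. The desk conditions sit in the identifiable
  regime; the trained model reaches r ≈ 0.6–0.85 on held-out genes,
  against a Poisson-noise ceiling of ≈ 0.93.
* **Recovery headroom over the distance baseline.** If every element
  regulates *some* gene, the only observable correlate of membership
  is the 1/log10(d) sampling preference — whose induced ranking is the
  distance baseline's own, making "beat the distance baseline"
  unattainable for any scorer. Sparse global linking (~60% of elements
  linked, windows barely overlapping) makes decoys mostly inactive
  elements, so activity signal genuinely separates regulators from
  decoys (oracle auROC ≈ 0.94 vs distance ≈ 0.52).

# Numerical choices

Pre-LayerNorm residual blocks with a final LayerNorm (stable without
warmup pathologies; warmup is still implemented as specified). Glorot
initialisation for projections; bias tables start at 0, so a freshly
initialised model is position-agnostic — tests that probe positional
behaviour first set nonzero biases. Softmax rows subtract their max;
softplus is computed overflow-free; a fully masked attention row is an
error rather than NaN. Ties in nearest-element selection break by
(interval start, element id); equal scores in auROC rank-average. The
backward pass of every block is validated against central finite
differences at relative tolerance 1e-4.

# Problem sizes

Test-suite and acceptance runs use the desk preset (above; one
training run of ~3–4 minutes on one CPU core), micro models
(`d_model` 8–16, elements of 7–30 bp) for gradient checks and
invariants, and small simulated landscapes (10–500 genes) for
generator statistics. The reference schedule (50,000 steps, 256
channels, 350-bp elements, 400-element contexts) is expressed by the
same configuration objects and was not run here.

# Known limitations

Frozen-element desk training cannot learn sequence-level features (the
planted motif is invisible to it by construction); the attention
interaction score is a model introspection, not a causal estimate;
Hi-C-style normalisation (ICE/KR) and TAD *calling* are out of scope —
boundaries are consumed, not inferred; the generator's single
chromosome means chromosome-held-out evaluation is only available for
multi-chromosome inputs supplied by the user.
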