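# attnreg

Attention-based modeling of cis-regulatory element effects on gene
expression, in R.

Which candidate cis-regulatory elements (cCREs) regulate which genes?
`attnreg` trains a hierarchical transformer to predict a gene's
expression from the DNA sequence and chromatin signal tracks (DNase,
H3K27ac, CTCF, ...) of the cCREs flanking its TSS, and then reads
candidate enhancer–gene interactions **zero-shot** out of the trained
model's attention weights — no interaction labels are ever used in
training. It is aimed at regulatory genomicists who want an
interpretable expression model, benchmark machinery for enhancer–gene
ranking, and a fully controlled synthetic testbed.

## The model

* **Element encoder** — each cCRE, padded to 350 bp, is embedded per
  base as `Emb_bp = DNA embedding + signal embedding` (two linear
  projections into `d_model` channels); a learnable `[CLS]` token
  attends the bases through a 2-layer, 4-head transformer encoder with
  T5-style bucketed relative-position bias, and its output `Emb_ele`
  represents the element.
* **Regulation encoder** — one shared learnable `[GENE]` token per
  gene plus the `Emb_ele` of up to 200 elements on each side of the
  TSS; a 4-layer, 4-head transformer whose relative-position bias
  buckets *signed genomic distance* (saturating at 1 Mb). Attention
  between distinct genes is masked. The gene token output passes
  through `softplus(w·Emb_gene + b)` to give a positive expression
  rate, trained with a Poisson negative log-likelihood
  `mean(λ − y·log λ)` under AdamW (batch 8, linear warmup to 1e-3,
  linear decay to 1e-8, gradient-norm clip 1.0, dropout 0.1).
* **Interaction score** — mean gene→element attention across layers
  and heads, min-max or softmax normalised per gene, optionally
  divided by `log10(distance)` ("adjusted attention"). Element–element
  attention binned at 10 kb supports insulation / TAD-boundary
  analyses; baselines include `1/distance` and an approximate
  Activity-by-Contact score `sqrt(H3K27ac·DNase)/distance`.

The transformer forward/backward passes are written directly on base-R
matrix algebra and are verified against finite-difference gradients in
the test suite.

## Worked example

Simulate a landscape with planted regulators, train the desk-scale
model, and ask whether attention finds the planted links:

```r
library(attnreg)

res <- run_recovery_experiment(seed = 1)   # ~4 minutes on one CPU
str(res$metrics)
#> List of 7
#>  $ heldout_pearson_r       : num 0.859
#>  $ attention_auroc         : num 0.78
#>  $ adjusted_attention_auroc: num 0.784
#>  $ distance_auroc          : num 0.579
#>  $ abc_auroc               : num 0.702
#>  $ adjusted_attention_auprc: num 0.882
#>  $ distance_auprc          : num 0.72
```

Reading the numbers: on 200 simulated genes (40 held out), predicted
and observed expression correlate at r = 0.86 on genes the model never
saw. Gene→element attention, extracted zero-shot and adjusted by
log10 distance, ranks the planted regulators above decoy elements with
auROC 0.78 — well above the distance-only baseline (0.58) and the
ABC-style activity/distance baseline (0.70), mirroring the qualitative
ordering reported for the full-scale model on CRISPR-validated
enhancer–gene pairs.

Lower-level entry points: `simulate_genome()`, `make_dataset()`,
`train()`, `forward_context(..., keep_attention = TRUE)`,
`gene_to_cre_scores()`, `bin_attention()`, `insulation_profile()`,
`group_ctcf_pairs()`, `classify_metrics()`. A thin command-line front
end (`inst/cli/attnreg`) wraps simulate / train / attend / evaluate /
insulate for shell pipelines. See the methods vignette
(`vignettes/attnreg-methods.Rmd`) for the model, the generator's
assumptions, and the design decisions.

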