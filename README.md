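# enzattn

Attention-based interpretability for enzyme function prediction, at desk
scale.

Enzymes are classified by Enzyme Commission (EC) numbers, a four-level
hierarchical code (`class.subclass.sub-subclass.serial`, main classes 1–7
with 7 = translocases). Transformer encoders with a CLS classification head
predict EC numbers from sequence alone, and their attention maps double as
an interpretability signal: pooled the right way, they point at the
residues the model relies on, which tend to coincide with curated catalytic
sites.

`enzattn` implements this methodology end to end, sized for a single CPU
and no external downloads:

* **Encoder** — a trainable self-attention encoder (`enzformer()`), fit
  from random initialization with flat cross-entropy, Adam, geometric
  learning-rate decay `lr(e) = lr0·decay^e`, gradient accumulation, dropout
  on the CLS embedding only, and optional inverse-frequency class-balanced
  sampling. Forward and backward passes are written in base R matrix
  algebra and checked against finite differences.
* **Attention aggregation** — the two-stage pooling family
  `AttnAgg<d1><f1><d2><f2>` over the `(L·H, T, T)` attention tensor
  (average/maximum per stage), with `enumerate_variants()` deduplicating
  the 16 nominal variants into 13 functional classes on random
  row-stochastic probes.
* **Saliency baselines** — gradient, gradient-times-input, integrated
  gradients, last-layer attention, attention rollout and a LIME-style
  perturbation surrogate, all emitting the same per-residue
  `importance_vector` contract.
* **Interpretability evaluation** — top-k F1 curves, pooled
  precision–recall-gain curves (`gain(x) = (x − π)/((1 − π)·x)` at
  prevalence π), PRG-AUC, maximum F-Gain with per-sequence rescaling
  sweeps, exact binomial enrichment tests, and a Table-style method
  comparison with a shuffled-score baseline.
* **Hierarchical EC evaluation** — `parse_ec()`, level truncation, macro
  precision/recall/F1 and accuracy at levels 0–4 under enzymes-only or
  all-sequences protocols.
* **Benchmark builder** — time-based splits with 40%-identity cluster
  exclusion (external cluster tables or a built-in greedy aligner-based
  clusterer), the enzyme/non-enzyme labelling rule, length/class filters
  and per-class censuses.
* **Synthetic fixtures** — seeded generators for motif-classed sequences
  with planted catalytic residues, attention tensors with planted
  hotspots, and paired releases with known ground truth.

## Worked example

Train a small encoder on a synthetic motif-classed corpus, then score
residues with the best aggregation variant and compare it against the
shuffled baseline:

```r
library(enzattn)

# 16 nominal pooling variants -> 13 functional equivalence classes
enumerate_variants(n_probe = 100, seed = 1)$n_classes
#> [1] 13

# enrichment of annotated residues among the top-10 importance scores
# (6 annotated in the top 10; 21 of 271 residues annotated overall)
enrichment_test(6, 10, 21, 271)$p_value
#> [1] 3e-05

# 300 sequences, 3 motif-defined classes, planted catalytic residues
spec <- synthetic_spec(n_sequences = 300, len_range = c(60, 100),
                       n_classes = 3, motif_len = 5, seed = 0)
syn <- gen_classified_sequences(spec)
tr <- 1:240; va <- 241:300

fit <- enzformer(syn$records$sequence[tr], syn$labels[tr],
                 valid = list(x = syn$records$sequence[va],
                              y = syn$labels[va]),
                 econf = encoder_config(n_layers = 2, n_heads = 4,
                                        embed_dim = 32, ff_dim = 64),
                 tconf = train_config(n_epochs = 10, lr0 = 2e-3,
                                      lr_decay = 0.9, batch_size = 2,
                                      accumulation_steps = 1, seed = 0))
fit
#> Self-attention enzyme-class classifier (enzformer)
#>   architecture: 2 layer(s) x 4 head(s), embed 32, ff 64
#>   classes (3): C1, C2, C3
#>   trained 10 epoch(s); final loss 0.0255, train acc 1.000, valid acc 1.000

# per-residue importance on held-out sequences via attention aggregation
ivs <- lapply(va, function(i) {
  cap <- forward_with_attention(fit, syn$records$sequence[i])$capture
  strip_special_tokens(aggregate_attention(cap, "AttnAgg1A1A"), cap,
                       seq_id = syn$records$id[i])
})
compare_methods(list(AttnAgg1A1A = ivs), syn$gold[syn$records$id[va]],
                saliency_config(shuffle_reps = 10, seed = 1))
#> Interpretability report (prevalence 0.0608, rescale "none")
#> Method             PRG-AUC (x100)   Max F-Gain (%)   Time (s)
#> AttnAgg1A1A                 95.86            97.13      0.004
#> Random                8.01+/-4.33     52.66+/-1.15
```

The model reaches perfect held-out accuracy on the motif task in about a
minute, and the aggregated attention ranks the planted catalytic residues
far above the shuffled-score baseline on both retrieval metrics: PRG-AUC
(area under the precision-gain/recall-gain curve, 100 = every catalytic
residue outranks every other residue) and max F-Gain (best
gain-transformed F1 over all score thresholds, 0 = no better than calling
everything catalytic).

A command-line wrapper over the same functions lives in
`inst/cli/enzattn.R` (`simulate`, `build-split`, `train`, `predict`,
`interpret`, `eval-interp`, `eval-ec`), each command driven by a JSON
config and leaving a reproducible run manifest.

The methods vignette (`vignettes/enzattn-methods.Rmd`) documents the model,
the aggregation family and its deduplication convention, the saliency
baselines and their numerical choices, the evaluation metrics, the
benchmark-building rules and the synthetic-fixture design.

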