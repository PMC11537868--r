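# abmlm — region-aware masked language modelling for antibody variable domains

`abmlm` is an R package for training and evaluating small masked-language
models (MLMs) of antibody Fv (variable-fragment) amino-acid sequences, for
people studying how antibody-specific pre-training choices affect what a
sequence model learns.

Antibody variable domains have a fixed anatomy: four conserved framework
regions (FR1–FR4) scaffold three hypervariable loops (CDR1–3), with the
heavy chain's CDR3 (CDR-H3) carrying most of the antigen-binding diversity.
A conventional MLM that masks 15% of tokens uniformly spends its training
signal mostly on redundant framework content. This package implements the
region-aware alternative and everything needed to study it end to end:

* **Masking curricula** — the region-aware rule (mask `round(0.7·|CDR-H3|)`
  positions of CDR-H3, then span-mask other regions until a total budget
  `round(r·L)` is met, `r ∈ {0.15, 0.30, 0.50, 0.70, 0.90}`), plus uniform
  random and BERT-style 80/10/10 baselines.
* **Encoder** — a transformer with disentangled relative-position attention:
  per head `A'ᵢⱼ = Qᶜᵢ·Kᶜⱼ + Qᶜᵢ·Kʳ_δ(i,j) + Qʳᵢ·Kᶜⱼ`,
  `δ(i,j) = clamp(i−j, −k, k) + k` (k = 128), scores scaled by `1/√(3d_k)`;
  a learned-absolute-position ablation mode; forward *and* backward passes in
  plain R, verified against finite differences.
* **Training loop** — AdamW, cosine schedule with warmup, label smoothing
  0.1, random 0–3 residue terminal truncation as augmentation, bit-for-bit
  resumable checkpoints.
* **Curation** — identity-based redundancy reduction: greedy clustering at
  80% identity, keep the longest member of multi-member clusters, re-cluster
  singletons at 50%, keep again; global-alignment identity
  (match 1 / mismatch 0 / linear gap 1; matches over alignment columns).
* **Evaluation** — whole-region restoration top-1/top-3 accuracy under
  terminal truncation (`10:-5`, `10:-10`, `20:-5`), and CDR-H3 amino-acid
  composition vs model reconstructions by Jensen–Shannon divergence, grouped
  by (family, CDR3 length).
* **Frozen-encoder heads** — contrastive heavy–light chain pairing (mean
  pooling, two-layer MLP projections, L2-normalized cosine, InfoNCE with
  identity-filtered negatives, auROC/auPRC over 5 negative resamplings) and
  CDR-H3 binding classification (per-position projection, flatten, two-layer
  MLP, repeated random splits, a 1/100 low-data protocol).
* **Synthetic grammar** — a generator of annotated Fv corpora with 7
  template families (standing in for IGHV genes), conserved frameworks,
  variable CDRs (entropy highest in CDR-H3), a planted heavy–light
  compatibility rule, and a fixed-length CDR3 binding library with a planted
  motif — so every experiment has ground truth.

Real repertoire corpora and full-scale training (millions of sequences,
GPU-weeks) are out of scope; everything here runs on one CPU in minutes.

## Worked example

```r
library(abmlm)

# 1. a synthetic annotated corpus from the grammar
grammar <- build_grammar(grammar_config(seed = 42))
rng <- new_rng(derive_seed(7, "corpus"))
corpus <- sample_corpus(grammar, 200, rng, "heavy")
test <- sample_corpus(grammar, 30, rng, "heavy", prefix = "T")

# 2. realized masking rates of the region-aware rule
st <- mask_stats(test, masking_config(), new_rng(derive_seed(7, "mask")))
cat(sprintf("mean realized total rate: %.4f\n", mean(st$total_rate)))
cat(sprintf("mean realized CDR3 rate:  %.4f\n", mean(st$cdr3_rate)))

# 3. a small encoder trained for a few minutes
model <- train_mlm(corpus, masking_config(),
                   encoder_config(d_ff = 128),
                   train_config(base_lr = 5e-3, batch_size = 4, epochs = 10,
                                warmup_epochs = 1, seed = 7))
cat(sprintf("training loss: %.3f -> %.3f\n",
            model$metrics$loss[1], tail(model$metrics$loss, 1)))

# 4. whole-region restoration with truncation robustness
rep <- restoration_report(model, test, region_sets = list("FR2", "CDR3"),
                          truncations = c("none", "10:-5"))
print(rep, digits = 3)
```

Output (R 4.3, single CPU, ~3 minutes):

```
mean realized total rate: 0.7002
mean realized CDR3 rate:  0.6979
training loss: 3.223 -> 2.863
  truncation regions k accuracy n_positions
1       none     FR2 1    0.237         510
2       none     FR2 3    0.453         510
3       none    CDR3 1    0.119         419
4       none    CDR3 3    0.267         419
5      10:-5     FR2 1    0.176         510
6      10:-5     FR2 3    0.365         510
7      10:-5    CDR3 1    0.136         419
8      10:-5    CDR3 3    0.267         419
```

The realized masking rates sit at the configured 70% (the small deviation is
the rounding law `round(0.7·|CDR3|)/|CDR3|` averaged over CDR3 lengths
8–20). Ten short epochs move the loss from chance (ln 25 ≈ 3.22) toward the
template structure; restoration accuracies are far above the 1/20 = 0.05
chance level for FR2 and above the ~0.11 best-constant baseline for CDR3,
and degrade only mildly under `10:-5` truncation because the encoder uses
relative positions. The acceptance suite trains the same architecture 5×
longer (50 epochs on 300 chains) and reaches mean framework restoration
≥ 0.90 (see `tests/testthat/test-acceptance.R`).

## Command line

```sh
inst/cli/abmlm synth    --seed 3 --n-heavy 1000 --out data/
inst/cli/abmlm curate   --in data/chains.fasta --t1 0.8 --t2 0.5 --out kept.fasta
inst/cli/abmlm pretrain --config cfg.json --train data/chains.fasta \
                        --regions data/regions.tsv --out runs/exp1
inst/cli/abmlm eval     --checkpoint runs/exp1/checkpoint_epoch_003 \
                        --test data/chains.fasta --regions data/regions.tsv \
                        --truncate 10:-5 --mask CDR3 --out report.tsv
inst/cli/abmlm pair     --checkpoint runs/exp1/checkpoint_epoch_003 \
                        --pairs data/pairs.csv --pool data/light_pool.fasta
inst/cli/abmlm bind     --checkpoint runs/exp1/checkpoint_epoch_003 \
                        --data data/binding.csv --subsample 0.01
inst/cli/abmlm mask-stats --in data/chains.fasta --regions data/regions.tsv
```

Configuration is one JSON document (sections `grammar`, `masking`, `model`,
`train`, `heads`, `eval`); unknown keys are rejected with their path. Every
run directory receives the resolved config, seed, package version, metrics,
and checkpoints.

## Documentation

The methods vignette
(`vignettes/region-aware-antibody-mlm.Rmd`) describes the model, the masking
curriculum, the synthetic grammar and its planted rules, the numerical
choices, and what a green test does and does not establish.
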