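---
title: "Region-aware masked language modelling for antibody variable domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-aware masked language modelling for antibody variable domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abmlm)
```

## The problem

Antibody variable domains (Fv) are not ordinary text. Four framework regions
(FR1–FR4) are strongly conserved — given the germline V-gene family, most
framework residues are essentially determined — while the three
complementarity-determining regions (CDR1–3) are variable, with CDR-H3 (the
heavy chain's third CDR) by far the most diverse. A masked-language-model
(MLM) trained on such sequences with the conventional 15% uniform masking
spends most of its capacity restating redundant framework content.

`abmlm` implements a region-aware alternative: corrupt a *high* fraction of
the sequence, deliberately target CDR-H3, and use contiguous span corruption
elsewhere, so that the training signal concentrates on the informative
regions. The package covers the whole experimental loop at desk scale:
corpus curation, the masking curricula, a transformer encoder with
disentangled relative-position attention, the MLM training loop, region
restoration and truncation-robustness evaluation, and two frozen-encoder
downstream heads (heavy–light chain pairing, CDR-H3 binding classification),
all exercised on a synthetic antibody grammar with known ground truth.

## The model

The encoder is a standard post-LN transformer; for one layer

$$x' = \mathrm{LN}(\mathrm{Attention}(x) + x), \qquad
  x'' = \mathrm{LN}(\mathrm{FFN}(x') + x'),$$

with $\mathrm{FFN}(x) = \mathrm{Act}(xW_1 + b_1)W_2 + b_2$ (GELU by
default). Attention for a single head disentangles content and position:

$$A'_{ij} = Q^c_i \cdot K^c_j \;+\; Q^c_i \cdot K^r_{\delta(i,j)}
           \;+\; Q^r_i \cdot K^c_j,$$

where $Q^c = HW_{q,c}$, $K^c = HW_{k,c}$ are content projections,
$K^r = PW_{k,r}$ projects a learned relative-position table
$P \in \mathbb{R}^{(2k+1)\times d}$, and
$\delta(i,j) = \mathrm{clamp}(i-j,-k,k)+k$ with $k = 128$ by default.
Scores are scaled by $1/\sqrt{3 d_k}$ — the variance of a sum of three dot
products — before the row softmax. Softmax output times $V = HW_{v,c}$,
heads concatenated, gives the sublayer output.

Two readings of the position-to-content term exist, and both are
implemented:

* `as_printed` (default): $Q^r = H W_{q,r}$, i.e. a second content-derived
  query. This is the formulation exactly as the source equation prints it.
* `deberta_original`: $Q^r = P W_{q,r}$ indexed by $\delta(j,i)$ — the
  original disentangled-attention formulation.

Both variants are verified against a naive double-loop oracle and by
finite-difference gradient checks; translation equivariance (hidden states
invariant to a global position shift, within the clamp radius) holds in
relative mode and fails in the `absolute_learned` ablation mode, which is the
mechanism behind the truncation robustness the evaluation protocol measures.

There is no output projection after the head concatenation: the attention
parameter set is exactly $\{W_{q,c}, W_{k,c}, W_{v,c}, W_{q,r}, W_{k,r}\}$
per head. The relative-position table is shared across layers.

## The masking curriculum

For an annotated heavy chain with residue count $L$ and CDR3 span $c$:

1. select $\mathrm{round}(0.70\,|c|)$ positions inside CDR3 — one contiguous
   block with uniform random offset by default (`cdr3_mode =
   "random_subset"` scatters them instead);
2. span-mask the remaining regions until exactly
   $\mathrm{round}(r_\mathrm{total}\,L)$ positions are selected in total,
   with spans drawn as: a run chosen with probability proportional to its
   unselected length, a uniform start, and a length of
   $1+\mathrm{Geom}(1/3)$ capped at 10.

If step 1 alone exceeds the total budget the span step is skipped (logged).
Light chains get untargeted span masking at the same total rate. Budgets
count residue tokens only; `[CLS]`/`[SEP]` are never selected, and `round()`
is R's round-half-to-even. The default replacement policy at high rates is
`ALL_MASK` (every selected token becomes `[MASK]`); the classic BERT
80/10/10 policy is available for the 15% baseline. A `uniform_random`
strategy (no targeting, no spans) implements the "\*" ablation baseline.

Numerical consequence of the rounding rule: over CDR3 lengths uniform on
8..20 the mean realized CDR3 fraction is
$\tfrac{1}{13}\sum_\ell \mathrm{round}(0.7\ell)/\ell \approx 69.9\%$, which
is what the acceptance report measures.

## Curation and splitting

Identity is defined by a global alignment with unit match, zero mismatch,
and linear gap penalty one, scored as matches / alignment columns
(Biostrings supplies the alignment engine). Clustering is a deterministic
greedy single pass in order of decreasing length (ties: lexicographic, then
input order); a sequence joins the first cluster whose representative it
matches at the threshold, else founds its own. Curation clusters at 0.80,
keeps the longest member of every multi-member cluster, re-clusters the
remaining singletons at 0.50 and keeps once more; stage-2 singletons are
discarded. The same keep-longest rule is applied at both stages (the source
procedure is ambiguous for stage 2; one rule everywhere is simpler and
preserves the intent of keeping a long representative).

## Training

`train_config()` defaults mirror the published full-scale configuration
(AdamW with $\beta = (0.9, 0.99)$, weight decay 0.01, base LR 3e-4, cosine
decay with warmup, label smoothing 0.1, random 0–3 residue terminal
truncation as augmentation); batch size and epochs are desk-sized. Three
named RNG streams (`data`, `mask`, `init`) are derived from the global seed,
so two runs that differ only in masking strategy see identical data order —
which is what makes the masking-strategy comparison paired. Checkpoints
(meta.json + flat little-endian doubles) are byte-stable across
save/load/save, and resuming from one reproduces the uninterrupted run
bit-for-bit.

A note on desk-scale optimization: the published base LR (3e-4) belongs to a
batch-784, 200-epoch regime. A from-scratch desk model given a few hundred
optimizer steps barely moves at that rate. The desk experiments in the test
suite therefore train with a larger learning rate (5e-3), batch 4, and a
narrower FFN (d_ff = 128) — chosen from convergence pilots on the synthetic
grammar — while the full-scale preset keeps the published values. Decoupled
weight decay applies to weight matrices only (not biases or layer-norm
parameters), and a global gradient-norm clip (default 1.0) guards the early
high-LR steps.

The desk runs also disable the truncation augmentation. The reason is
instructive: in this grammar, a fully masked FR4 can only be positioned by
its distance to the CDR3/FR4 boundary or to `[SEP]`, because the variable
CDR3 length decouples FR4 from the left-hand frameworks. The C-terminal
truncation jitters the `[SEP]` distance by 0–3, so a model that leans on the
`[SEP]` anchor faces a four-way positional ambiguity whose Bayes answer caps
FR4 restoration near 25% — which is exactly where augmented desk models
plateau (≈ 0.16–0.19 FR4 top-1, against ≈ 0.97 for FR1–FR3). Without
augmentation the stable boundary anchor is learnable and FR4 climbs with
training. At full scale, with orders of magnitude more steps, a model can
discover the truncation-invariant left-edge route (distance to the visible
CDR3 terminal anchor), so augmentation and FR4 accuracy are not inherently
at odds; at desk step counts they are, and the augmentation keeps its own
dedicated tests instead.

A related budget note: comparing masking curricula is only informative once
both arms have converged. The uniform-15% baseline reaches its
fully-masked-CDR3 restoration plateau within ~15 desk epochs, while the
region-aware 70% model starts below it and overtakes around epochs 40–50.
Before that crossover both arms are near chance and their ordering is noise.
The acceptance suite therefore compares one *converged* seed pair at equal
corpus, seed, and compute rather than several unconverged ones.

## The synthetic grammar: what it does and does not emulate

`build_grammar()` is a pure function of its config (seed included). Each of
7 families — the stand-in for IGHV/IGLV germline gene families — owns fixed
framework templates (heavy lengths 25/17/38/11, so a 0–3 terminal truncation
only ever touches FR1/FR4), small CDR1/CDR2 motif sets, CDR3 anchor residues
(first/last), and a family-biased CDR3 interior distribution (60% of mass on
3 favored residues). Frameworks get i.i.d. substitutions at rate 0.02; CDR3
length is uniform on 8..20. This reproduces the *structural premise* —
positional entropy CDR3 > CDR1/2 > FR, asserted as a test invariant — and
gives every evaluation a known ground truth.

Two rules are planted for the downstream heads. Pairing: heavy family $f$
pairs with light family $f$, reinforced by a shared FR3 key residue; the
<0.85-identity negative filter automatically restricts negatives to other
families, so the rule is recoverable from pooled representations. Binding: a
fixed-length (10) CDR3 library where label 1 means a length-3 motif sits at
offset 3, flipped with 5% label noise; classes are balanced by construction.

What the grammar does **not** have: real germline alleles, somatic
hypermutation structure, V(D)J junctional statistics, length/composition
correlations of real repertoires, or any biophysics. A green test therefore
establishes that the pipeline's machinery is correct and that the planted
signal is recovered — not that the method reaches any particular accuracy on
real antibody data.

## Evaluation protocols

* **Region restoration**: whole regions are replaced by `[MASK]`; top-k
  accuracy is the fraction of masked positions whose true residue ranks in
  the model's k best (canonical residues only, ties broken by alphabet
  order). "Top-3" is read as standard top-3 accuracy.
* **Truncation robustness**: slice notation `"a:b"` keeps residues
  $[a, L+b)$ *before* masking (the grid none, 10:-5, 10:-10, 20:-5);
  annotations are re-clipped.
* **CDR3 composition**: within each (family, CDR3-length) group, the pooled
  amino-acid frequencies of the true CDR3s are compared with the model's
  top-1 reconstructions by Jensen–Shannon divergence (natural log; 0 for
  identical distributions, $\ln 2$ for disjoint support). Groups with fewer
  than 10 pooled positions are excluded.

## Downstream heads

Both heads treat the encoder as a frozen feature extractor — a parameter
hash before and after head training enforces this.

**Pairing** (contrastive): mean-pool hidden states over residue tokens,
project through per-chain-type two-layer MLPs, L2-normalize, and score by
cosine. Training minimizes InfoNCE with temperature 0.1 over one true light
chain and 15 sampled negatives (identity < 0.85 to the true partner, checked
against the pool with the curation module's identity). The reported score is
$(\cos + 1)/2 \in [0,1]$; the rescale is affine so the loss uses raw cosine.
Evaluation resamples negatives 5 times and averages auROC (tie-corrected
pairwise concordance) and auPRC (step integration over distinct thresholds).

**Binding**: the hidden states of the CDR3 positions, zero-padded to a fixed
window of 20 (pad rows contribute nothing: projected pad rows are zeroed —
the "zero-vector pad" is applied after the shared linear projection, which
keeps padding strictly inert), flattened, then a two-layer MLP with softmax.
Training is plain cross-entropy over repeated random 70/15/15 splits with
best-on-validation epoch selection; the low-data protocol subsamples the
training portion at rate 0.01 (15,000 → exactly 150).

## Numerical choices and edge cases

* Budgets use round-half-to-even; a selection that rounds to zero yields an
  empty plan with a logged warning rather than an error.
* Truncation augmentation that would empty a previously non-empty region is
  skipped for that sample (logged), so CDR annotations can never be
  destroyed by augmentation.
* The loss is computed only at selected positions; its gradient is exactly
  zero elsewhere (asserted by a finite-difference probe).
* Softmax and log-sum-exp are max-shifted; layer norm uses $\epsilon =
  10^{-5}$; ranking ties in top-k predictions break by the fixed residue
  order.
* `greedy_cluster` is quadratic in the number of clusters — deliberate: the
  desk-scale replacement for a linear-time clustering binary, with identical
  threshold semantics.
* Empty negative pools, degenerate one-class splits, and non-finite losses
  reject loudly with counts/diagnostics rather than proceeding.

## Known limitations

* Pure-R training tops out around 10–20 sequences/second for the default
  2-layer, d=64 encoder; the "paperlike" scale (12 layers, d=768, 18M
  sequences) is out of reach by design.
* The encoder processes one sequence at a time (no padding/attention
  masking); batching affects only gradient averaging.
* No dropout by default (deterministic tests); configurable.
* The identity metric is one specific global-alignment convention; other
  tools' "percent identity" definitions will differ in gap treatment.
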