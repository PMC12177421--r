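---
title: "Trajectory-order pretraining for coded patient records: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory-order pretraining for coded patient records: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A patient's electronic health record accumulates coded events — ICD-style
diagnoses and ATC-style medications — grouped into visits. Transformers
pretrained with masked language modeling (MLM) learn which codes co-occur,
but co-occurrence is order-blind: "diabetes, then chronic kidney disease"
and the reverse produce the same bag of contexts at small scales. Yet the
direction of such transitions carries clinical information (complication
follows disease; treatment follows diagnosis).

`toobert` implements a pretraining scheme that adds a **trajectory-order
objective (TOO)** to MLM: the model is additionally trained to distinguish
a patient's true sequence from a permuted copy. Permutations are produced
by swapping either individual codes across visits (RCS/CCS) or whole visit
blocks (RVS/CVS), and the *conditional* variants bias the choice of what to
swap toward pairs with observed temporal asymmetry, so the corruption
preferentially destroys exactly the directed structure the model should
learn.

## The conditional swap statistics

For codes $c_i, c_j$, let $\mathrm{CCnt}(c_i, c_j)$ count, over all
pretraining trajectories, occurrence pairs where $c_i$ falls in a strictly
later visit than $c_j$. The code-level swap weight is

$$\mathrm{CCS}(i,j) = S_{k_i,k_j}\,
\frac{\max(\mathrm{CCnt}(i,j)-\mathrm{CCnt}(j,i),\,0)}
     {\mathrm{CCnt}(i,j)+\mathrm{CCnt}(j,i)+1} + \varepsilon .$$

Three ingredients are essential and fixed: the max-difference numerator
keeps only the dominant direction (a unidirectional transition graph); the
kind-pair scaling $S$ compensates for the diagnosis/medication token
imbalance; the additive floor $\varepsilon$ (default 0.01) keeps every pair
selectable. The *normalisation* by
$\mathrm{CCnt}(i,j)+\mathrm{CCnt}(j,i)+1$ is this package's own
reconstruction — it makes weights scale-free in corpus size so
$\varepsilon$ is comparable across pairs — and is flagged as such wherever
the statistic is documented. $S$ is likewise a reconstruction: it equals
the inverse relative token share of the kind pair, normalised so
$S(\mathrm{dx},\mathrm{dx}) = 1$.

The visit-level weight is the one-way sum
$\mathrm{CVS}(v_x,v_y)=\sum_{a\in v_x}\sum_{b\in v_y}\mathrm{CCS}(b,a)$
for $x<y$ — the pooled evidence that the later visit's codes
conditionally follow the earlier visit's. A `symmetric` switch adds the
reverse terms for users who prefer the two-way reading of "sum over all
medical codes within visits x and y"; the one-way form is the default
because swapping is only informative when it destroys an observed
direction.

## Corruption semantics

* **Swap fraction.** A fraction $f$ requests $k=\max(1,\mathrm{round}(f
  \cdot n/2))$ *disjoint* pairs, where $n$ is the number of code positions
  (code swapping) or visits (visit swapping); the realised fraction $2k/n$
  is the share of positions touched. Disjointness keeps the permutation
  interpretable; $k \ge 1$ guarantees every "permutated" sample differs
  from its source.
* **Code swaps** exchange two token values across visits; SEP positions
  and the visit-number track never change. Conditional eligibility is
  restricted to occurrence pairs ordered later-after-earlier, so a chosen
  swap moves the later occurrence earlier — destroying the observed
  direction.
* **Visit swaps** exchange whole code blocks between visit slots;
  positions keep their slot's visit number (contents move, slots do not).
* **MLM masking** selects each code position with probability 0.15 and
  replaces it by MASK (80%), a random code (10%), or leaves it supervised
  but unchanged (10%). When no position is selected — likely only for very
  short sequences — one random position is forced so every sample carries
  supervision; the induced bias is $(1-0.15)^n$, negligible beyond toy
  lengths.

## Architecture

The encoder follows the compact published design: summed code, trainable
visit-number, and fixed sinusoidal embeddings (both positional components
indexed by *visit number*, not token index, since the temporal unit of the
record is the visit); one transformer layer with 5 attention heads; width
36. With $d_k=d_v=d_x=36$ stated alongside 5 heads, the only consistent
reading is that each head uses the full 36-dimensional key/value size with
a $5\cdot36\to36$ output projection, and that is what is implemented. The
TOO head reads the CLS representation through a tanh pooling layer — the
standard sequence-classification convention; the MLM head is a linear
softmax over the vocabulary. At the published vocabulary scale
(≈2,300 codes) the model has ≈214k learnable parameters, within the
stated "approximately 300,000" budget; `tb_init_model()` reports the count
at build time.

There is no deep-learning framework dependency: forward passes,
backpropagation (including through layer norm, softmax attention, and the
bidirectional GRU head), and AdamW are implemented in base R matrix code.
Every gradient path is verified against central finite differences in the
test suite; this is the package's primary correctness anchor.

## Training procedure

Pretraining strictly alternates MLM and TOO batches and optimises the
weighted loss $W_{MLM} L_{MLM} + W_{TOO} L_{TOO}$ (defaults 1 and 1;
weights of zero skip the objective, so $W_{TOO}=0$ is MLM-only
pretraining). TOO batches are drawn from the *permutable* subset of
sequences so ordered/permuted labels stay balanced — an unbalanced stream
would teach the head a biased intercept rather than order sensitivity.
A 10% monitor split is held out; training stops when the monitor loss
improves by less than 0.1% for 3 consecutive epochs ("plateau"), the
operational form of training until the loss curve stabilises.

Maximum sequence length defaults to the 0.7 quantile of flattened
trajectory lengths; longer trajectories are tiled into visit-aligned
sliding windows (stride: half the window, in visits — the spec of the
windows is visit-aligned so no visit is ever split; the stride value is
this package's choice).

Fine-tuning attaches a bidirectional GRU head (64 units per direction) and
trains the whole network with layer-wise learning-rate decay: layer $\ell$
(0 = embeddings) trains at $lr\cdot\gamma^{L-\ell}$, default
$\gamma=0.9$ (the technique's citation gives no value; 0.9 is a
conventional choice). The labeled set is divided into $k$ stratified
splits (default 5); each of $k$ models trains on $k-1$ splits with early
stopping on the held-out one, and reported performance is the mean ± SD of
rank-based AUC (midrank tie credit) over the $k$ models on an untouched
test set.

Published optimisation defaults are preserved as configuration defaults
(Adam, learning rate 7e-5, weight decay 0.015, dropout 0.1). The
experiments shipped with the package run at desk scale — corpora of
500–2,000 synthetic patients, 15–30 epochs — where a learning rate of
5e-4–1e-3 is used instead, since 7e-5 is matched to corpora three orders
of magnitude larger; the problem sizes used by each scripted experiment
are stated where they run.

## The synthetic generator: what it emulates, and what it does not

`synthetic_spec()` defines corpora with: a Zipf rank-frequency law
(exponent 1.1) over a 60 dx + 20 rx vocabulary; two visit-count regimes
("short" ≈ 2.5 visits, "long" ≈ 18, mirroring the hospital-encounter vs
registry contrast); 20 planted directed pairs $a\to b$ with odds lift
$\lambda=8$ — once $a$ has occurred, $b$'s sampling odds in later visits
are multiplied by $\lambda$; lognormal length-of-stay; and an
order-dependent outcome rule for labeled cohorts (logistic risk with a
term that fires only when the trigger's source precedes its target, target
code injected as a new final visit, intercept calibrated to a requested
prevalence). `recover_lifts()` estimates realised lifts with a
control-code ratio-of-ratios so the multinomial renormalisation cancels;
the generator round-trip is tested against the planted $\lambda$.

Three generator choices deserve emphasis. Planted pairs are
*node-disjoint* — the 40 most frequent codes are paired off by adjacent
frequency rank, each code in at most one pair — because shared nodes let
one edge lift another pair's target and flip that pair's marginal
temporal asymmetry, making the planted direction unidentifiable from
counts. Visits carry 8 (short regime) / 6 (long regime) codes on average;
real encounter data carry tens of codes per visit, and sparser visits
would make the planted structure fire too rarely to measure. And trigger
pairs for the outcome rule deliberately avoid planted edges so that,
given co-occurrence, their order is close to a fair coin — otherwise
presence and order collapse into one signal and order-aware models have
nothing to gain. Even so, the planted transitions are the *only* order
signal: unlike real records, the generator has no chronic-code
persistence, no progressive code accumulation, and no visit-level
nonstationarity. A logistic classifier given the exact planted-pair
reversal statistic (full generator knowledge; computed by the acceptance
script as `bayes_feature_ceiling_acc_pct`) reaches ≈0.78 accuracy at full
visit-swap on the short regime. Passing order-learnability tests here
therefore demonstrates the machinery learns what is learnable — it does
not certify the near-perfect swap detection reported on real hospital
data, which rests on much richer order structure.

## Numerical and degenerate-input conventions

* Visit windowing is greedy and anchored on each visit's first event;
  the 6-month window is 183 days, boundary inclusive.
* Unknown codes map to UNK with a warning rather than erroring.
* Attention maps for display are min-max normalised per head (a
  `per_matrix` switch normalises jointly); a constant matrix maps to
  zeros.
* The AUC estimator gives ties 0.5 credit via midranks; it is
  cross-checked against an independent implementation in the tests.
* Checkpoints round-trip bit-identically; pretraining is exactly
  reproducible under a fixed config and seed (single-threaded BLAS
  assumed).
* Corpus splits use largest-remainder rounding so subset sizes always sum
  to the patient count.

## Known limitations

* One encoder layer with a CLS readout limits order detection to
  (code × visit-slot)-level evidence pooled through attention;
  conjunction-style reversal evidence is only partially accessible. This
  matches the published architecture but caps synthetic-task accuracy
  well below 1.
* The generator omits calendar-time irregularity; dates exist only to
  exercise visit windowing.
* Shipped HF/AD target-code prefixes are reconstructions for synthetic
  use, not clinical code lists.
* Training is plain R: practical for hundreds-to-thousands of short
  synthetic trajectories, not for millions of real visits.
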