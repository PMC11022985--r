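---
title: "Predicting aqueous solubility with deep-ensemble uncertainty: models and methods"
author: "soluq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting aqueous solubility with deep-ensemble uncertainty: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Aqueous solubility, reported as log S (the base-10 logarithm of molar
solubility), is a property that is expensive to measure and hard to compute
from first principles. Data-driven models predict it well, but a point
prediction alone is of limited use in decision making: a medicinal chemist
triaging candidates needs to know *how much* to trust each number. `soluq`
implements a deep ensemble of small recurrent neural networks that reads a
molecule directly as a string — SMILES or SELFIES — and returns a predictive
Gaussian whose variance is split into an aleatoric part (noise intrinsic to
the data) and an epistemic part (disagreement between models).

Working from raw strings, rather than descriptors, keeps the model small and
dependency-free: no descriptor software, no 3D structure generation, no
feature selection. The cost is that one molecule admits many strings, and
the model is *not* intrinsically invariant to that choice; the training
pipeline confronts it with many randomized strings per molecule so it can
learn the invariance instead.

## The model

Each ensemble member is a small network:

1. **Embedding.** SELFIES tokens are mapped to integer ids by a fixed
   vocabulary (pad = 0, unknown = 1, chemical tokens in lexicographic
   order) and embedded into a continuous space (default dimension 64).
2. **Two bidirectional recurrent layers** (GRU or LSTM, default LSTM,
   64 units per direction). The first layer returns the full sequence, the
   second only its final states (forward state at the last real token,
   backward state at the first), concatenated to a single vector. Pad
   positions are masked: they neither update the recurrent state nor leak
   into outputs, so padding length cannot affect predictions.
3. **Layer normalization** with learned gain and bias on that vector.
4. **Dense stack** 32 -> 16 (ReLU), then two parallel 1-unit heads: a
   linear head for the mean mu and a softplus head for the standard
   deviation sigma. A small additive floor (default 1e-3 log S) keeps
   sigma strictly positive, so sigma^2 >= floor^2 and the likelihood is
   always finite.

Training minimizes the exact Gaussian negative log-likelihood

$$ l = \tfrac12 \log(2\pi\sigma^2(x)) + \frac{(y-\mu(x))^2}{2\sigma^2(x)}, $$

including the constant, with Adam (fixed learning rate 1e-4 by default,
beta1 = 0.9, beta2 = 0.999). Dropout (default rate 0.35) is applied after
the embedding and after each hidden dense layer during training only.

**Adversarial smoothing.** Because token ids are discrete, adversarial
examples are generated in embedding space: each iteration performs one Adam
update on the clean batch, then computes the fast-gradient-sign
perturbation eps * sign of the loss gradient with respect to the embedded
input, applies it as an offset on the (freshly updated) embedding, and
performs a second update on that perturbed batch. A single optimizer state
spans both updates. With eps = 0 this degenerates *exactly* to two clean
updates per iteration — the test suite asserts bit-level equality. The
reference workflow does not state eps; the default is 0.01 in embedding
units, configurable.

**Ensembling.** N members (default 4) differ only in their seed, which
drives initialization, minibatch shuffling and dropout. Predictions
aggregate the member Gaussians as a uniform mixture:

$$ \mu^* = \frac1N\sum_m \mu_m,\qquad
   \sigma^2_{ale} = \frac1N\sum_m \sigma_m^2,\qquad
   \sigma^2_{epi} = \frac1N\sum_m (\mu_m-\mu^*)^2 . $$

The sum of the two variance components is exactly the mixture variance;
the test suite checks this against brute-force mixture moments at 1e-12.
Note that $\sigma^2_{epi}$ is the biased (1/N) variance of member means: it
is identically zero for a singleton ensemble, and for independently trained
members its *expectation* grows like $(1-1/N)\tau^2$ with ensemble size —
what shrinks as N grows is the estimator's noise, i.e. the upper tail of
the uncertainty distributions, not their center. The package's ensemble-size
experiments therefore compare 95th percentiles, not means, across N.

## String handling

- **Canonicalization** is delegated to OpenBabel (via ChemmineR/ChemmineOB).
  Canonical SMILES defines molecule identity for deduplication, augmentation
  parentage and leakage reports.
- **Randomized SMILES** are produced by renumbering the atom block of the
  molecule's structure table with a random permutation and letting OpenBabel
  write the SMILES in that order; duplicates are rejected, at most
  `10 * max_new` permutations are attempted, and every output string
  canonicalizes back to its parent (tested by round-trip).
- **SELFIES encoding** is implemented in the package (no R SELFIES library
  exists): molecules are kekulized, traversed depth-first in input atom
  order, and emitted as bond-prefixed atom symbols (`[C]`, `[=O]`,
  `[NH3+1]`), branch symbols carrying their own length and ring symbols
  carrying a back-reference distance, both in base-16 index symbols over the
  standard 16-symbol index alphabet. Disconnected components are joined
  with `.`. Stereochemistry is not encoded: round-trips preserve
  constitution, which is also the identity notion used everywhere else.
  The decoder rebuilds the molecular graph and writes SMILES; the suite
  checks `canonical(decode(encode(s))) == canonical(s)` across the corpus
  and on ring/branch/charged exemplars.

## Data pipeline

`read_solubility_csv()` ingests AqSolDB-style tables (configurable column
names), dropping unparsable rows with a logged count.
`augment_records()` adds at most `max_new` (default 10) randomized strings
per record, each carrying the parent's label, then removes exact string
duplicates globally — the reference workflow's behavior; an optional
canonical-level mode exists. `split_records()` shuffles and splits 80/20
by default *after* augmentation, again mirroring the reference workflow.
That ordering lets different strings of one molecule land on both sides,
which flatters test metrics; the split therefore always carries a leakage
report (parent molecules present on both sides), and `by_parent = TRUE`
gives the stricter no-leakage split.

## The synthetic benchmark

Real solubility data require network access and hours of training, so the
package ships a generator whose ground truth is fully known.
`synth_corpus()` builds linear carbon/oxygen chain molecules (3-12 chain
atoms, occasional methyl/hydroxyl branches on interior carbons, no O-O
bonds — all valid, stereocenter-free SMILES) and labels them

$$ y = a\,\mathrm{heavy} + b\,n_O + \varepsilon,\qquad
   \varepsilon \sim N\!\big(0,\; (c_0 + c_1\,n_O/\mathrm{heavy})^2\big), $$

defaults a = -0.3, b = 0.8, c0 = 0.1, c1 = 0.4. The mean is exactly
learnable from the token stream and the noise standard deviation varies
with the oxygen fraction, so the generator probes precisely the two heads
of the model: the mean head must recover the linear law, and the variance
head must recover the *heteroscedastic pattern* — testable because the true
per-molecule sd is stored in the ground-truth table.

What the generator does **not** emulate: rings, aromatic systems,
heteroatoms beyond oxygen, charged species, activity cliffs, measurement
bias, and inter-laboratory reproducibility limits of real solubility data.
Passing the synthetic recovery tests shows the estimator machinery works;
it does not certify accuracy on real chemical space.

## Scaled-down experiment design

The packaged experiments (test suite and `scripts/acceptance.R`) use tiny
members — embedding 16, 16 recurrent units, dense 32/16 — trained about 50
epochs with Adam at 1e-3 on 1600 training molecules (n = 2000 corpus,
80/20 split), batch 32. The ensemble-size sweeps (N = 1, 4, 10 and
n = 200 vs n = 2000) use 15 epochs per member to keep a full run on one
CPU within minutes; within each sweep every configuration shares the same
split and the same member seed sequence so comparisons isolate the factor
of interest.

Two design choices deserve explanation:

- **Dropout is disabled in the uncertainty-recovery experiments.** With
  train-time dropout active, the residuals the variance head sees include
  dropout-induced prediction noise, which at this scale dominates the data
  noise and carries no structure; the head then learns a large, flat sigma.
  Measured on the synthetic corpus, the correlation between predicted
  aleatoric sd and true noise sd is ~0.1 at dropout 0.35, ~0.65 at 0.1 and
  ~0.90 at 0. The package default remains 0.35 — appropriate for real-data
  training where overfitting is the binding constraint — but the synthetic
  recovery experiments set dropout = 0 so that the aleatoric channel
  measures data noise rather than regularization noise.
- **Learning rate 1e-3 instead of the reference 1e-4.** At 2,500-25,000
  updates (toy scale) the reference rate cannot reach the
  well-converged regime the experiments probe; 1e-3 is stable for these
  tiny members.

## Numerical choices

- Softplus is computed as `log1p(exp(x))` with a linear branch above 30 to
  avoid overflow; its gradient is the logistic function.
- Layer normalization uses eps = 1e-5 inside the square root.
- Adam uses eps = 1e-8 and bias-corrected moments; both updates of an
  adversarial iteration advance the same optimizer state.
- Gate order is (z, r, n) for GRU — candidate state uses the
  reset-before-projection convention — and (i, f, g, o) for LSTM with
  forget-gate bias initialized to 1. Weights are Glorot-uniform; the
  embedding is N(0, 0.05^2).
- All randomness flows through explicitly passed seeds; library calls
  save and restore the caller's RNG state. Training is exactly
  reproducible for a fixed seed and thread configuration (the recurrent
  kernels are single-threaded C++).
- Sequences longer than `max_len` are dropped (with a log message) during
  training-data preparation and truncated (with a warning) at prediction.
  Out-of-vocabulary tokens map to the unknown id with a warning, or raise
  in strict mode.
- Ties and degenerate inputs: Pearson r on a constant vector is reported
  as NA with a warning rather than 0; the +-0.5 log S accuracy counts the
  boundary as correct.

## Known limitations

- The per-member cost of the backpropagation-through-time kernels grows
  linearly in sequence length; very long SELFIES (max_len 128 default)
  are supported but slow on one CPU at the reference architecture size.
- Epistemic uncertainty from a deep ensemble is a disagreement measure,
  not a calibrated posterior variance; with few members it is itself
  noisy (see the tail-vs-center discussion above).
- The SELFIES implementation covers the organic subset, charges, explicit
  hydrogen counts, branches, rings and disconnected components, but not
  stereo descriptors or isotopes.
- Full-scale reproduction of the reference AqSolDB workflow (9,982
  molecules, ~96k after augmentation, 64-unit members) is supported by the
  same code paths via the command-line interface but takes hours on one
  CPU and requires downloading the data; it is not part of the test suite.
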