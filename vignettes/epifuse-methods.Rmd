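---
title: "Methods: ensemble score fusion for conformational B-cell epitope prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble score fusion for conformational B-cell epitope prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model implemented by **epifuse**, the
exact numerical conventions, and the design decisions made where a published
description leaves room for interpretation. It is a methods reference, not a
tutorial; the README holds a worked end-to-end example.

## Problem and model

The task is per-residue binary classification: given only sequence-derived
information about an antigen chain, score every residue for membership in a
conformational (discontinuous) B-cell epitope. The pipeline has four stages:

1. **Windowing.** Each residue is represented by the window of `L` residues
   centred on it (`L` odd, default 9). Chains are padded with `(L - 1) / 2`
   pseudo-residues `X` per terminus, so a chain of `N` residues yields exactly
   `N` windows; a 15-residue window over the chain `KVFGRCEL` starts with
   `XXXXXXXKVFGRCEL`. `X` never matches any alphabet position: it contributes
   all-zero blocks to positional encodings and is excluded from composition
   denominators.

2. **Feature encodings.** Nine schemes over the canonical 20-letter alphabet
   `ACDEFGHIKLMNPQRSTVWY`:

   | encoder | dimension | needs |
   |---|---|---|
   | `propensity` | `6L` | — (six physicochemical scales per position) |
   | `sparse` | `20L` | — (one-hot residue identity per position) |
   | `composition` | `20` | — (window residue frequencies) |
   | `function_group` | `13L` | — (one-hot over 13 function groups) |
   | `functional_composition` | `13` | — (window group frequencies) |
   | `evolutionary` | `20L` | PSSM (log-odds mapped through `1/(1+e^-x)`) |
   | `pair_profile` | `400` | — (adjacent-pair frequencies) |
   | `ss` | `3L` | secondary-structure string over H/E/C |
   | `rasa` | `L` | relative accessible surface area in `[0, 100]`, used as `rasa/100` |

   The 13 function groups partition the alphabet as {R,K}, {E,D}, {S,T},
   {L,V,I}, {Q,N}, {W,F} and seven singletons {A}, {C}, {G}, {H}, {M}, {P},
   {Y}.

3. **Imbalance-handled ensembles.** Epitope residues are rare, so each
   encoder's classifier is an ensemble of `n = max(1, round(neg / pos))`
   random forests. The negative pool is shuffled once and sliced into `n`
   cyclic chunks of `pos` instances (mode `"partition"`); each forest trains
   on all positives plus one chunk, so every negative is seen whenever
   `neg <= n * pos`. Mode `"bootstrap"` draws negatives with replacement
   instead. The sub-classifier score of a window is the mean over members of
   the fraction of trees voting for the epitope class.

4. **Score fusion.** Sub-classifier scores are put on a common scale by the
   tanh-estimator `s' = 0.5 * (tanh(c * (s - mu) / sigma) + 1)` and fused by
   a convex weighted sum. Weights may be fixed, uniform, the package default
   vector, or found by exhaustive grid search over the simplex with step
   0.05 (231 points for 3 encoders; `choose(26, 6)` = 230230 for 7),
   maximising the mean per-antigen AUC.

## Numerical conventions

- **tanh constant.** `c = 0.01`, the standard value in the score-normalization
  literature; with it the estimator is approximately linear over typical
  score ranges while still squashing outliers.
- **Moments.** `mu` and `sigma` are the sample mean and sample standard
  deviation (`ddof = 1`) of the training-score distribution; `sigma` is
  floored at `1e-9` (with a warning) so constant score vectors normalize to
  0.5 rather than NaN. Normalization parameters are estimated on training
  data only and frozen into the model bundle.
- **AUC.** The rank-based Mann–Whitney form with average ranks for ties,
  equivalent to pair counting with half-credit for tied pairs; it is
  undefined (an error) for single-class label vectors. Per-antigen AUCs are
  averaged with single-class antigens dropped as `NA`.
- **Thresholding.** `score >= threshold` predicts epitope; sensitivity,
  specificity, accuracy and F1 are `NA` when their denominator is zero.
- **Positions.** All residue positions are 1-based, in file formats and in
  the API; R is 1-based throughout and a 0-based internal convention would
  buy nothing but off-by-one risk at every boundary.
- **Grid order and ties.** The simplex grid is enumerated in ascending
  lexicographic order and the first maximum wins, so ties resolve to the
  lexicographically smallest weight vector, deterministically.

## Evaluation protocol

`evaluate_loocv()` performs leave-one-antigen-out cross-validation: all
chains of the held-out antigen form the test fold, and everything — the
per-encoder ensembles and the normalization moments — is refitted on the
remaining antigens, so folds are strictly leak-free. The headline number is
the unweighted mean of per-antigen AUCs.

Weight search uses a deliberately different protocol. `loocv_predictions()`
makes one LOOCV pass per encoder and collects the out-of-fold normalized
sub-scores into a single table; `grid_search_weights()` then optimises the
mean per-antigen AUC of the fused score over that table. This mirrors the
practice of determining one weight vector on a development set and reusing
it, and it keeps the search affordable (a nested per-fold search would
multiply the training cost by the grid size). The fused objective is, by
construction, at least the best single encoder's on the same table; it is
*not* a fully unbiased estimate of generalisation for the selected weights,
which is why `evaluate_loocv()` with a *fixed* weight vector exists as the
honest estimator.

## Synthetic generator

`simulate_epitope_dataset()` plants controllable epitope signal so that
recovery can be tested property-style without any external data. Each chain
(default 20 antigens, 140–160 residues) receives two non-overlapping patches
of 8–15 residues (about 15 % coverage); labels are patch membership.
Signal knobs, all off in the `"null"` preset:

- `composition_shift` interpolates patch residue frequencies from background
  toward a hydrophilic/charged profile (K, R, D, E, N, S);
- the fabricated PSSM is a conserved one-hot log-odds pattern (+7 on the
  true residue, −2 elsewhere) plus symmetric integer jitter, doubled inside
  patches (lower conservation);
- `rasa_shift` raises patch RASA over a `N(35, 15)` baseline, clipped to
  `[0, 100]`, rounded to 1 decimal;
- `coil_bias` moves the patch H/E/C distribution (background 0.35/0.20/0.45)
  toward coil.

Presets: `"null"` (no signal; mean LOOCV AUC should sit near 0.5),
`"single-signal"` (`composition_shift = 1`), `"complementary-signals"`
(`composition_shift = 1` and `rasa_shift = 40`, carried by different
encoders so fusion has something to gain). Generation is byte-reproducible
under the config seed. Problem sizes and preset parameters are the package's
own choices, sized to make ensemble training fast while leaving clear
statistical margins.

## Design decisions and limitations

- The ensemble size rule `n = max(1, round(neg / pos))` is the
  majority/minority ratio; the floor keeps balanced data trainable.
- The base learner is `randomForest` with library defaults apart from
  `ntree`; it sits behind a small contract (fit on a matrix + factor,
  return class probabilities) so it could be swapped.
- Default fusion weights put most mass on the evolutionary profile
  (propensity 0.1, functional_composition 0.0, evolutionary 0.5, sparse 0.0,
  ss 0.1, rasa 0.2, pair_profile 0.1); with synthetic data you will normally
  pass explicit weights, `"uniform"`, or `"search"`.
- `terminal_policy` controls flank scoring with large windows: the default
  `"full_ensemble"` scores every residue with the fused ensemble;
  `"composition_only"` falls back to the composition sub-classifier within
  `(L - 1) / 2` residues of a terminus, where positional encodings are
  dominated by padding.
- Real predictive performance on real antigens depends on externally
  computed PSSM / secondary-structure / RASA tracks, which this package
  reads but does not compute; no claim is made here about absolute accuracy
  on natural data.

```{r}
library(epifuse)
cfg <- synthetic_preset("complementary-signals", seed = 1)
d <- simulate_epitope_dataset(cfg)
rep <- evaluate_loocv(d, encoders = c("composition", "rasa"),
                      weights = "uniform", L = 9, seed = 1)
rep$mean_auc
```
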