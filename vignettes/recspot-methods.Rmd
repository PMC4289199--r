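---
title: "Sequence-composition classification of recombination spots: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-composition classification of recombination spots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recspot)
```

## The problem and the model

Meiotic recombination concentrates in kilobase-scale hotspots whose
sequence composition (GC content, dinucleotide bias) differs from
coldspots. `recspot` treats hotspot identification as a two-class
sequence classification problem with three stages.

**Representation.** A sequence of length $L$ over $\{A,C,G,T\}$ is
encoded as its pseudo nucleic acid composition: overlapping $k$-mer
frequency tiers $k = 1..k_{\max}$, each tier normalized by its window
count $L-k+1$ so it sums to one, followed by the pseudo dinucleotide
composition. The PseDNC block augments the 16 dinucleotide frequencies
$f_m$ with $\omega$ sequence-order coupling factors
$$ g_j \;=\; \frac{1}{L-j-1}\sum_{i=1}^{L-j-1}
   \Delta\!\left(R_iR_{i+1},\, R_{i+j}R_{i+j+1}\right),
   \qquad j = 1..\omega, $$
where $\Delta(d_1,d_2)$ is the mean squared difference of six
normalized dinucleotide structural properties (twist, tilt, roll,
shift, slide, rise). The block is jointly normalized,
$$ d_m = \frac{f_m}{\sum_{m'} f_{m'} + w\sum_j g_j},\qquad
   d_{16+j} = \frac{w\,g_j}{\sum_{m'} f_{m'} + w\sum_j g_j}, $$
so the whole PseDNC vector also sums to one. The coupling factors are
what distinguishes this representation from plain $k$-mer counting:
they retain *global* sequence-order information that composition alone
discards.

**Ranking.** Features are ranked by recursive feature elimination with
a linear-kernel soft-margin SVM: fit, drop the feature with the
smallest squared weight $w_i^2$, refit, until none remain; the ranking
is the reverse elimination order. A two-class F-score filter is
provided as the conventional baseline ranker.

**Selection and evaluation.** The SVM regularization parameter $C$ and
the retained dimension (top-$N$ of the ranking) are chosen by grid
search; every $(C, N)$ pair is scored by leave-one-out (jackknife)
accuracy. The selected model is reported with sensitivity, specificity,
accuracy and Matthews correlation from the per-class
misclassification counts, and with an ROC curve and AUC built from the
signed jackknife decision values.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k_max` | 5 | highest frequency tier; the five tiers contribute $4+16+64+256+1024 = 1364$ features. Higher tiers add exponentially many, increasingly redundant features. |
| `omega` | 10 | number of coupling lags (features `pse:lambda.j`, unitless). Must not exceed $L_{\min}-2$ so every lag has at least one term in every sequence. |
| `w` | 0.05 | weight of the coupling block relative to the dinucleotide frequencies. $w=0$ reduces PseDNC exactly to dinucleotide composition, which the tests exploit as a limit case. |
| `C` | grid $2^{-5}..2^{15}$ | SVM soft-margin cost, the single free kernel-side parameter of a linear SVM. |
| `N` | grid $1..\min(200, D)$ | retained top-feature dimension. |

The property table ships with the package
(`inst/extdata/dinucleotide_properties.tsv`) and is symmetric under
reverse complementation (the row for AC equals the row for GT, and so
on), a symmetry $\Delta$ and therefore the coupling factors inherit.
Users may substitute any table of the same shape.

Features are deliberately **not** standardized before the SVM: every
PseNAC feature already lives on a comparable $[0,1]$-scale, and
rescaling would silently change the $w_i^2$ elimination criterion. An
optional `scale` flag exists for users who want it.

## Ranking protocol and selection leakage

By default the ranking is computed once on the full dataset and reused
by every jackknife fold, matching the single accuracy-versus-top-$N$
curve this method family reports. That protocol lets feature selection
see the held-out sample, so its accuracy estimate is optimistic.
`nested = TRUE` re-ranks within every fold (at the selected dimension)
for a leakage-free estimate at roughly $n$ times the cost. The same
$C$ used for the final model is used during RFE by default
(`rfe_C` exposes it separately).

Ties are resolved deterministically throughout: on the elimination
criterion, the feature with the larger column index is eliminated
(earlier-defined features survive); on the accuracy surface, the
smaller $N$, then the smaller $C$, wins; tied decision values step the
ROC curve simultaneously (AUC equals the normalized Mann–Whitney
statistic with ties counted half).

## What the synthetic generator emulates

`generate_dataset()` draws coldspot sequences i.i.d. from a background
base composition and hotspot sequences from a first-order Markov chain
whose transition matrix up-weights planted dinucleotides (and
optionally tilts G+C), then renormalizes. Lengths are uniform on
1,000–2,500 nt, the characteristic extent of a recombination region,
and the default class sizes 490/591 mirror the usual benchmark's class
ratio; tests and the acceptance script use 50/60.

A dinucleotide-level Markov signal was chosen over motif insertion
because every feature family the encoder computes — all $k$-mer tiers
and all coupling factors — responds to dinucleotide statistics, so the
planted signal is detectable by the method under test without being
trivially separable by any single feature. What the generator does
*not* emulate: repeat structure, isochore-scale heterogeneity,
chromatin-driven positional effects, or any higher-order dependence
beyond first order. A pipeline that passes these tests is validated as
an implementation; nothing here certifies accuracy on real genomes.

## Numerical and degenerate-input choices

* $k$-mer and PseDNC blocks are checked to sum to one within $10^{-9}$;
  the $\Delta$ matrix is clamped at zero against round-off.
* The SVM is LIBSVM (via e1071); its internal class order depends on
  label encounter order, so the extracted $(w, b)$ are re-oriented
  against the model's own fitted labels so that positive decision
  values always mean "hotspot". The test suite cross-checks the primal
  solution against an independent interior-point solution of the SVM
  dual on small problems, including the case where the bias is only
  determined up to a KKT interval.
* MCC with a zero marginal returns 0 with a message; constant decision
  values give AUC 0.5 with a warning; a jackknife fold that loses a
  class entirely (possible only when a class has one sample) predicts
  the fold majority, with a message.
* Records with non-ACGT characters are rejected by name (or dropped
  with a warning under `skip_invalid`), because silently recoding
  ambiguous bases would corrupt the frequency normalization.

## Leave-one-out on null data: a caveat

On *exactly null* data (both classes drawn from one distribution),
leave-one-out with any class-balance-sensitive learner is
**anti-predictive**, not chance-level: holding out a sample leaves the
training fold tilted against that sample's own class, and with no
signal available that tilt decides every fold. With balanced classes
and the full feature set this drives LOO accuracy and AUC toward 0 —
an artifact of the protocol, not a bug, and worth knowing before
interpreting small LOO deviations from 0.5 on weak data. Once the
pipeline's top-$N$ selection restricts the model to a few features,
the artifact largely vanishes and the null pipeline lands in the
expected chance band (accuracy $\approx$ the majority rate, AUC
$\approx 0.5$–$0.65$), which is exactly what the acceptance checks
assert. The unit tests assert the one-sided guard that matters for
leakage detection: null data must never show *positive* signal.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run the pipeline at 50
hotspots / 60 coldspots, $k_{\max}=3$, $\omega=10$ (110 features),
$C \in \{1, 32\}$ and $N \in \{5, 10, 25, 50, 110\}$, replicated over
a handful of generator seeds — the package's chosen validation scale,
at which the planted-signal recovery (accuracy $\ge 0.95$, planted CG
features in the top ranks) and the null chance band are both sharp and
quick to recompute. The full-default scale (490/591 sequences, 1,390
features, $N$ up to 200) is supported by the same code path; a full
SVM-RFE pass at that scale is a long-running batch job.

## Known limitations

* Linear kernel only, two classes only, strict A/C/G/T alphabet (no
  RNA, no IUPAC ambiguity codes, no trinucleotide property tables).
* The default evaluation protocol shares the ranking across jackknife
  folds (see above); use `nested = TRUE` when an unbiased estimate
  matters more than faithfulness to the original protocol.
* One feature is eliminated per RFE round by default; `chunk > 1`
  trades ranking resolution for speed on wide matrices.
* The exact $\omega$ and $w$ behind published benchmark figures of
  this method family are not recoverable from the literature; the
  defaults here ($\omega = 10$, $w = 0.05$) are stated, configurable
  choices.
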