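# recspot

Classification of meiotic recombination hotspots and coldspots from DNA
sequence alone. Recombination initiates at double-strand breaks that
cluster in 1–2.5 kb regions whose sequence composition — GC content and
dinucleotide bias in particular — differs from recombinationally cold
regions. `recspot` implements a complete sequence-based predictor for
this two-class problem and is aimed at anyone who wants to train,
inspect or reuse such a predictor on their own labeled sequence sets.

## Method

Each DNA sequence is represented by its **pseudo nucleic acid
composition (PseNAC)**, the concatenation of

* *k*-mer frequency tiers *k* = 1..5: normalized overlapping *k*-mer
  frequencies `f(m) = count(m) / (L − k + 1)`, 4 + 16 + … + 1024
  features, and
* **pseudo dinucleotide composition (PseDNC)**: the 16 dinucleotide
  frequencies augmented with ω sequence-order coupling factors

  g_j = (1/(L−j−1)) Σᵢ Δ(RᵢRᵢ₊₁, Rᵢ₊ⱼRᵢ₊ⱼ₊₁),

  where Δ is the mean squared difference of six normalized dinucleotide
  structural properties (twist, tilt, roll, shift, slide, rise; the
  constant table ships with the package), jointly normalized as
  d_m = f_m / (Σf + wΣg) and d_{16+j} = w·g_j / (Σf + wΣg).

Features are ranked by **SVM-RFE**: a linear-kernel soft-margin SVM is
fitted repeatedly and the feature with the smallest squared weight w²
is eliminated each round, producing a full ranking (an F-score filter
ranker is included as the baseline). The regularization parameter *C*
and the retained dimension *Dim* are chosen by **grid search** under
**jackknife (leave-one-out) cross-validation**, and performance is
reported as sensitivity, specificity, accuracy, Matthews correlation
coefficient (from the hot/cold misclassification counts) and ROC/AUC
from the jackknife decision values.

A synthetic-data generator produces labeled hot/cold sets with planted
dinucleotide-composition signal (first-order Markov hot class over an
i.i.d. background) so the whole pipeline can be validated end to end
without any external benchmark.

## Worked example

```r
library(recspot)

d <- generate_dataset(synthetic_config(n_hot = 50, n_cold = 60,
                                       planted = c(CG = 3), seed = 11))
fit <- recspot(d$sequences[d$labels == 1],
               d$sequences[d$labels == -1],
               k_max = 3, omega = 10,
               C_grid = c(1, 32), N_grid = c(5, 10, 25, 50, 110))
fit
#> Recombination spot classifier (PseNAC + SVM-RFE + linear SVM)
#>   samples: 50 hotspots, 60 coldspots; 110 features (k_max = 3, omega = 10)
#>   selected: C = 32, Dim = 5 (rfe ranking)
#>   jackknife: Sn = 1.0000  Sp = 1.0000  Acc = 1.0000  MCC = 1.0000  AUC = 1.0000

head(as.data.frame(fit$ranking), 3)
#>   rank  feature elimination_step criterion
#> 1    1  kmer1:G              110 7.7466541
#> 2    2 kmer2:CG              109 6.3687333
#> 3    3   pse:CG              108 1.7998069
```

The planted CG bias is recovered: the CG dinucleotide features
(`kmer2:CG`, `pse:CG`) rank at the top, the grid search keeps a small
dimension (*Dim* = 5) at *C* = 32, and the jackknife separates the two
classes perfectly at this effect size. `predict(fit, fasta_or_seqs)`
scores new sequences; `plot(fit, "surface")` and `plot(fit, "roc")`
draw the top-*N* accuracy sweep and the ROC curve;
`save_model_json()` / `load_model_json()` persist the trained model.

The same pipeline is scriptable from a shell via
`inst/scripts/recspot.R` with `simulate`, `encode`, `rank`, `evaluate`
and `predict` subcommands.

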