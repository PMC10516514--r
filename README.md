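# mhcbind

Pan-specific modelling of MHC class I peptide binding affinity in R, with an
architecture built around the two things that make the problem hard:
**anchor positions** that shift with peptide length, and the **interaction**
between a peptide and a specific MHC allele.

MHC-I molecules present 8–13-mer peptides to cytotoxic T cells; predicting
which peptides an allele binds underpins epitope discovery and neoantigen
vaccine design. `mhcbind` fits a neural regression model in which

* each peptide position passes through its own **gated linear unit**
  `x̄ᵢ = σ(Wᵢxᵢ + bᵢ) ⊙ (Vᵢxᵢ + cᵢ)`, letting the model amplify anchor
  positions and mute bulge positions per position;
* convolution kernels are **generated from the allele's 34-residue
  pseudo-sequence embedding**, `Kᵢ = f(UᵢY)`, so the filter bank — and hence
  the learned binding motif — is conditioned on the MHC molecule
  (kernel sizes 9/11/13, counts 128/64/32);
* two convolution branches (raw and gated peptide representation) combine
  residually with per-channel batch normalization, followed by a
  position-wise FC stack (256, 128), max-pooling over positions, and a
  sigmoid head on the normalized affinity scale
  `y = 1 − log(IC50 nM)/log(50000)` (binder ⇔ IC50 < 500 nM ⇔ y > 0.426).

Training is mini-batch Adadelta (lr 0.9, weight decay 1e−4, batch 128) on
mean squared error with a reduce-on-plateau schedule (patience 5), and
repeated F-fold cross-validation with fresh initializations gives a
prediction-averaging ensemble (10 × 5 folds = 50 models under the published
protocol). The forward *and* backward passes are implemented in base R over
BLAS matrix operations — no deep-learning framework required — and are
verified against naive-loop oracles and finite differences in the test
suite.

The package also provides the full evaluation-statistic suite used by
affinity benchmarks (per-allele per-length AUC/PCC/SRCC with the
\>20-points / ≥3-binders reporting filter, overall percent rank, the Frank
epitope statistic, exact one-tailed binomial sign tests), binding-motif
extraction (top 1% of 100 000 random peptides → position-frequency matrix
with per-position information content), and a synthetic planted-motif data
generator that makes every stage testable without external downloads.

## Worked example

Generate a synthetic benchmark (4 alleles with planted anchors at position
2 and the C-terminus, 6000 records), train one model, and inspect what it
learned:

```r
library(mhcbind)

syn <- generate_dataset(seed = 42)          # table + ground-truth PSSMs
tab <- assign_folds(syn$table, folds = 5, seed = 42)
model <- mhci_fit(tab, held_out_fold = 0, epochs = 30, seed = 42)
model
#> Pan-specific MHC-I binding affinity model
#> Binding model configuration
#>   input length L = 15 , embed dim d = 16 ( learned )
#>   kernels: 128 x size 9, 64 x size 11, 32 x size 13  (d0 = 224 )
#>   FC widths: 256, 128  dropout: 0.25
#>   gated layer: TRUE (untied)  residual branch: TRUE
#>   trained 30 epochs on 4800 records (fold 0 held out)
#>   final train MSE 0.00397, held-out MSE 0.01360
#>   parameters: 255713

ho <- !is.na(tab$fold) & tab$fold == 0
pred <- predict(model, allele = tab$allele[ho], peptide = tab$peptide[ho])
auc(pred, classify_binder(tab$affinity[ho]))
#> [1] 0.9885052
pcc(pred, tab$affinity[ho])
#> [1] 0.962013
```

Held-out binder classification is essentially solved (AUC 0.99) and
predicted affinities track the noisy measurements (PCC 0.96; the
observation noise bounds attainable correlation). The model's binding
motif for one allele recovers the planted anchors — the two highest
information-content positions of a 9-mer motif are position 2 and the
C-terminus:

```r
mo <- extract_motif(model, "SYN-01", length = 9, n = 20000,
                    top_fraction = 0.01, seed = 7)
motif_anchors(mo)      # two highest-IC positions
#> [1] 2 9
```

Predictions convert back to nM and a binder call with the standard writers:

```r
write_predictions(data.frame(allele = "SYN-01",
                             peptide = c("ACDEFGHIK", "ACDEFGHIKL"),
                             pred_affinity = pred[1:2]), "preds.tsv")
```

A command-line interface wrapping the same functions ships at
`inst/cli/mhcbind.R` with sub-commands `simulate | train | predict |
evaluate | motif`; every run writes a manifest with seeds and input
checksums. See the package vignette (`vignettes/mhcbind-methods.Rmd`) for
the model, training protocol, evaluation statistics and simulator design in
detail.

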