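---
title: "Trait prediction from genotype images: models and design choices"
author: "AIOpred maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait prediction from genotype images: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

AIOpred predicts quantitative traits (for example thousand-seed weight in
grams, or seeds per plant) from genome-wide biallelic SNP genotypes, and
ranks SNPs by their influence on the prediction.  The pipeline has five
stages:

1. **Image encoding.**  Each accession's genotype vector is written into an
   *artificial image object* (AIO): a `side x side x 3` array in which every
   pixel carries one SNP as a one-hot pseudo-colour triple — red for the
   reference homozygote (dosage 0), green for the heterozygote (1), blue for
   the alternative homozygote (2) and the all-zero pixel for a missing call.
   SNPs fill the image left-to-right, top-to-bottom, and the SNP list is
   reused cyclically from the start until every pixel is filled, so each SNP
   appears `floor` or `ceiling` of `side^2 / nSnps` times.
2. **Dictionary features.**  All training images are cut into square blocks
   (default 16x16 pixels, all three channels) and a small dictionary of
   unit-norm template blocks ("atoms", default 16) is learned so that each
   block is approximated by a sparse weighted sum of atoms.  Per accession,
   the magnitudes of the non-zero coefficients of each atom are fitted by a
   log-normal law (micro features: the MLE mean and standard deviation of
   the logs) and the atom usage frequencies form the macro features; the
   concatenation (length `3 * nAtoms`) summarises how an accession's image
   blocks relate to panel-wide patterns, i.e. the genetic similarity
   structure of the panel.
3. **Network.**  An encoder–decoder convolutional network consumes the
   image: three 3x3 convolutions (32, 64, 128 channels, ReLU, 'same'
   padding) with 2x2 max-pooling after the first two, so the encoder output
   is 128 maps of `side/4`; then two 2x2-stride-2 transpose convolutions,
   each followed by concatenation with the matching encoder map (skip
   connection) and a 3x3 convolution, ending in 32 maps at the input size.
   Global average pooling (GAP) reduces these to 32 numbers.
4. **Regression.**  The GAP vector concatenated with the dictionary features
   feeds an extreme gradient boosting regressor trained under mean absolute
   error (MAE).  Because decision trees admit no gradient, "simultaneous"
   training of network and regressor is realised by alternation: the network
   learns through an auxiliary dense head (also MAE), and every
   `refitInterval` epochs the boosted regressor is refit on the frozen
   (GAP, dictionary) features; the epoch at which the refit regressor
   attains maximal validation accuracy defines the stored model.
5. **Attribution.**  Dense regression attention maps are computed per
   accession: by default the absolute gradient of the auxiliary regression
   output with respect to the input image, reduced per pixel by the maximum
   over the three channels (a layer-CAM style variant on the decoder output
   is available).  Pixel intensities are averaged over each SNP's cyclic
   placements, giving one importance score per SNP and accession, and SNPs
   whose mean importance exceeds the panel-wide pooled mean are selected by
   Dunnett's many-to-one criterion at family-wise level `alpha`.  Selected
   SNPs can be screened further by genotype-class Student's t-tests on the
   trait.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `side` | 128 px | image side; any multiple of 4 with `side^2 >= nSnps` |
| `nAtoms` | 16 | dictionary size (atoms) |
| `blockSide` | 16 px | dictionary block side; must divide `side` |
| `targetError` | 0.01 | relative block reconstruction error targeted by learning and used as the OMP stopping tolerance |
| `maxSparsity` | 10 | atoms per block cap in OMP |
| `epochs` | 150 | training epochs |
| `valSplit` | 0.2 | fraction of training accessions held out for epoch selection |
| `refitInterval` | 5 | epochs between boosted-regressor refits |
| `batchSize` | 8 | Adam minibatch size |
| `learningRate` | 3e-3 | Adam step size |
| `folds` | 10 | cross-validation folds |
| `alpha` | 0.05 | family-wise level of the Dunnett selection |

The image side, 16-atom dictionary, 0.01 error target, 16x16 blocks,
150 epochs, 20% validation split and 10 folds are the settings selected for
the chickpea panel this methodology was developed on (407 accessions, 6642
SNPs); they are defaults, not constraints.

Prediction **accuracy** is reported as the range-normalised MAE complement,
`a = 100 * (1 - MAE / range(observed))` percent.  The underlying loss is
MAE; this maps it onto a scale-free percentage (100 = perfect, and a
predictor whose MAE equals the observed range scores 0).  No other accuracy
definition is implied.

# The synthetic data generator

`simulateGenotypes()` draws ancestral allele frequencies uniformly on a MAF
range (default 0.05–0.5) and, when subpopulations are requested, diverges
them by a Balding–Nichols Beta draw with parameter `F`; genotypes are
binomial(2, p) and missing calls are placed uniformly at random.
`simulatePhenotype()` adds an additive trait: `nCausal` SNPs with Gaussian
effects, plus Gaussian noise scaled so the realised heritability targets
`h2`, then an affine map onto a requested trait range (e.g. 110–440 to
emulate a thousand-seed-weight-like spread) with optional rounding for
count traits.

The reference study conditions used by the package's end-to-end checks are
120 accessions x 300 SNPs in five subpopulations at `F = 0.15`, 10 causal
SNPs, `h2 = 0.8`, trait range 110–440, images of side 32 with 8x8 blocks
and 16 atoms, 3 folds at 20 epochs.  The subpopulation structure reflects
the multi-origin germplasm collections this method targets — panel
structure is precisely what the dictionary features are meant to capture —
and the problem sizes keep a full double run (observed and permuted traits)
in the minutes range on one CPU.  What the generator does **not** emulate:
linkage disequilibrium (SNPs are independent given the subpopulation
frequencies), recombination maps, real allele-frequency spectra, dominance
or epistasis (an optional pairwise term can be bolted on for stress tests),
and genotyping error.  Consequently, passing tests demonstrate the
machinery end to end and its statistical calibration, but say little about
accuracy on real panels, where LD makes many markers informative about each
causal locus.

# Numerical and design choices

* **Missing genotypes** are kept as `NA` through I/O and become the all-zero
  pixel only at encoding time, so the genotype-class t-tests retain the
  distinct classes.  Treating missing as a fourth one-hot state is not
  offered; the three-channel scheme is part of the method's definition.
* **Dictionary learning** alternates batch OMP coding with per-atom rank-1
  SVD updates of the restricted residual (dead atoms are re-seeded with the
  worst-reconstructed block; atoms are kept unit-norm).  Reaching the error
  target is not guaranteed on high-entropy inputs; the achieved error,
  iteration count and a convergence flag are always reported, and hitting
  the iteration cap raises a warning rather than an error.  Block
  extraction is per image, aligned to each image's own grid, so the
  "mosaic" of all images is realised as a concatenated block set and no
  arbitrary arrangement order can influence results.  The dictionary is
  re-learned on the training accessions of every fold; held-out accessions
  are coded against the frozen dictionary, avoiding leakage.
* **Log-normal fits** use `|coefficient|` (the law needs positive support;
  OMP coefficients can be negative).  Atoms with zero observations for an
  accession get the `(0, 0)` sentinel and frequency 0, so feature vectors
  always have length `3 * nAtoms`; a single observation yields its MLE
  `(log |c|, 0)`.
* **Auxiliary-head targets are standardised** (zero mean, unit variance on
  the fit portion) during network training.  With MAE the gradient carries
  only the residual's sign, so on a raw trait scale (say, grams in the
  hundreds) the head's output could not traverse the offset within a
  realistic epoch budget; standardisation makes the optimisation
  scale-invariant.  The boosted regressor is always fit on the raw trait.
* **Epoch selection** maximises the validation accuracy of the boosted
  regressor (the model's actual output), not the auxiliary head's loss.
* **Attention maps** default to input-gradient saliency with per-pixel
  channel-max of absolute gradients; gradients at max-pool ties are valid
  subgradients (ties are common on one-hot inputs).  Importances average
  per accession first — each accession contributes one observation per SNP
  to the selection stage.
* **Dunnett control group.**  The "control" is the pooled score sample of
  all SNPs.  Treatments are compared against it under the classical
  equicorrelated multivariate-t model; adjusted p-values are computed by
  numerical multivariate-t integration for small panels and by a seeded,
  vectorised Monte-Carlo approximation of the max-T null distribution for
  larger ones.  Because every treatment contributes to the pooled control,
  the test is slightly conservative, which is the safe direction for
  family-wise error control.  The number of selected SNPs is driven by
  `alpha`; a fixed top-k cap is available for panels where a fixed-size
  list is wanted.  The follow-up genotype-class t-tests are reported
  unadjusted (screened at plain p < 0.05) and flagged as such.
* **Determinism.**  All stochastic steps (simulation, fold assignment,
  initialisation, batching, the boosted regressor, Monte-Carlo p-values)
  are driven by explicit integer seeds; repeated runs with one seed are
  identical on a fixed platform.

# Known limitations

* A convolution stack followed by global average pooling is (up to padding
  effects) translation-invariant, while the causal information in an AIO is
  tied to fixed pixel positions.  Position specificity must therefore be
  learned indirectly through local neighbourhood patterns, which is
  sample-hungry; on small unstructured panels the network's held-out gain
  over a constant predictor is modest, and most of the recoverable signal
  travels through the dictionary features and the boosted regressor.  This
  is a property of the method, not of the implementation.
* The three-channel one-hot scheme cannot represent more than three
  genotype states.
* The exact kernel sizes of the original chickpea model were tuned to that
  dataset and are not published; this implementation fixes 3x3 kernels with
  'same' padding, which reproduces all published activation shapes (128
  channels of 32x32 at the encoder output, 32 channels of 128x128 at the
  decoder output for side 128) but not the original parameter count.
* Dictionary learning on high-entropy genotype images typically stops at
  the iteration cap rather than the 0.01 error target; the reported error
  should be inspected.
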