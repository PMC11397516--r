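# AIOpred

Genomic prediction of quantitative traits from SNP genotypes encoded as
**artificial image objects** (AIOs), with SNP attribution by dense
regression attention maps.

## The problem and the method

Breeding programmes want to predict a quantitative phenotype *y* (for
example thousand-seed weight in grams) for an accession from its
genome-wide biallelic SNP genotypes *g ∈ {0, 1, 2, NA}ᵐ* (dosage of the
alternative allele), and to know *which* markers drive the prediction.
AIOpred implements an image-based pipeline:

* **Encoding.** Genotypes are painted into a `s × s × 3` image: pixel
  `(x, y)` shows SNP `(y·s + x) mod m` as a one-hot pseudo-colour,
  `R = 1` iff `g = 0`, `G = 1` iff `g = 1`, `B = 1` iff `g = 2`
  (missing → all-zero pixel); the SNP list is reused cyclically until the
  image is full.
* **Dictionary features.** Images are split into `b × b` blocks and a
  dictionary of `K` unit-norm atoms **d**ₖ is learned so each block
  **x** ≈ Σₖ cₖ **d**ₖ with at most `maxSparsity` non-zero cₖ (orthogonal
  matching pursuit; SVD-based atom updates).  Per accession, log-normal
  fits to |cₖ| give micro features (μ̂ₖ, σ̂ₖ) and atom usage frequencies
  give macro features — a `3K`-vector summarising the accession's position
  in the panel's genetic-similarity structure.
* **Model.** An encoder–decoder CNN (3×3 convolutions, 32→64→128 channels,
  two 2×2 max-pools; mirrored by transpose convolutions with skip
  connections back to 32 maps at full size) is reduced by global average
  pooling to 32 numbers, concatenated with the dictionary features, and
  fed to an extreme gradient boosting regressor.  Training minimises the
  mean absolute error; network and regressor are trained in alternation
  and the epoch with the best validation accuracy is kept.  Accuracy is
  reported as `a = 100·(1 − MAE/range(y))` percent.
* **Attribution.** Per-accession attention maps (channel-max absolute
  input gradients of the regression output) are averaged over each SNP's
  pixel placements; SNPs whose mean importance significantly exceeds the
  pooled panel mean are selected by **Dunnett's many-to-one criterion** at
  family-wise α, then screened by genotype-class Student's t-tests on the
  trait.

A Balding–Nichols style simulator with known causal architecture
(`simulateGenotypes()` / `simulatePhenotype()`) makes every stage testable
without external data.

## Worked example

```r
library(AIOpred)

g <- simulateGenotypes(nAccessions = 60, nSnps = 100,
                       nSubpops = 3, fst = 0.2, seed = 1)
g <- simulatePhenotype(g, nCausal = 8, h2 = 0.9,
                       traitRange = c(110, 440), seed = 2)
g
#> GenotypeSet: 60 accessions x 100 SNPs
#>   missing calls: 0.00%
#>   traits: trait

cv <- trainGenomicModel(
  g,
  dcfg = dictConfig(nAtoms = 16, blockSide = 4, maxIter = 10, seed = 1),
  ccfg = cnnConfig(side = 20, epochs = 10, seed = 1),
  folds = 3)
cvReport(cv)
#>   fold n_control control_accuracy best_epoch dict_error
#> 1    1        20         74.70127         10  0.4606072
#> 2    2        20         81.27063          5  0.4637872
#> 3    3        20         77.27920         10  0.4532647

imp <- snpImportance(cv, g)               # SNPs x accessions, out-of-fold
sel <- dunnettSelect(imp, alpha = 0.05, snpMap = snpMap(g))
sel
#> SnpSelection: 6 of 100 SNPs selected (alpha 0.05, greater)
head(sel@table[order(sel@table$p_adj), ], 3)
#>      snp_id chrom     pos  mean_score statistic   p_adj selected
#> 47 snp00047   Ca4 4009641 0.001461690  4.751204 0.00010     TRUE
#> 72 snp00072   Ca6 5347802 0.001443528  4.444525 0.00065     TRUE
#> 76 snp00076   Ca6 8934066 0.001427233  4.169368 0.00145     TRUE
```

`control_accuracy` is the range-normalised MAE complement on each held-out
fold (77.8% mean here); `dict_error` is the mean relative block
reconstruction error of the fold's dictionary.  The selection table lists
each SNP's mean attention score, its Dunnett statistic against the pooled
panel mean and the family-wise adjusted p-value; `groundTruth(g)` exposes
the simulated causal SNPs and effect sizes for benchmarking selections.
On panels this small the attention ranking is noisy — selected SNPs need
not be the causal ones, which is why the t-test screen and the simulator's
ground truth exist.

Real data enter through `readGenotypes()` (VCF `GT` fields, biallelic
sites, or a delimited accession × SNP dosage matrix with a side-car map)
and `readTraits()`; `runPipeline()` (or `inst/scripts/aiopred.R`) drives
`simulate → encode → learn-dict → train → predict → explain` from a YAML
config with a hashed manifest.

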