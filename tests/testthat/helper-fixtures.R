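# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

# small structured panel with a heritable trait
tinyPanel <- function() {
  if (is.null(.fixtures$panel)) {
    g <- simulateGenotypes(30, 40, nSubpops = 2, fst = 0.2, seed = 101)
    .fixtures$panel <- simulatePhenotype(g, nCausal = 5, h2 = 0.9,
                                         traitRange = c(110, 440),
                                         seed = 102)
  }
  .fixtures$panel
}

# a quick 2-fold cross-validated model on the tiny panel
tinyCV <- function() {
  if (is.null(.fixtures$cv)) {
    .fixtures$cv <- suppressWarnings(trainGenomicModel(
      tinyPanel(),
      dcfg = dictConfig(nAtoms = 8, blockSide = 4, maxIter = 8, seed = 1),
      ccfg = cnnConfig(side = 16, epochs = 3, refitInterval = 2,
                       xgbRounds = 50, seed = 1),
      folds = 2))
  }
  .fixtures$cv
}

tinyBundle <- function() tinyCV()@bundles[[1]]

# write a minimal VCF with the given genotype strings (sites x samples)
writeTestVcf <- function(path, gt, chrom = NULL, pos = NULL, ids = NULL,
                         alt = NULL) {
  ns <- ncol(gt)
  nv <- nrow(gt)
  chrom <- chrom %||% rep("Ca1", nv)
  pos <- pos %||% seq(100, by = 100, length.out = nv)
  ids <- ids %||% sprintf("rs%03d", seq_len(nv))
  alt <- alt %||% rep("T", nv)
  lines <- c("##fileformat=VCFv4.2",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", paste0("S", seq_len(ns))),
                   collapse = "\t"))
  for (v in seq_len(nv))
    lines <- c(lines, paste(c(chrom[v], pos[v], ids[v], "A", alt[v], ".",
                              "PASS", ".", "GT", gt[v, ]), collapse = "\t"))
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
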