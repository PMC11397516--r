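#' Default pipeline configuration
#'
#' One nested list mirroring the published settings of the chickpea study
#' (image side 128; 16 atoms, 16x16 blocks, target error 0.01, sparsity 10;
#' 150 epochs, 20% validation split, 10 folds; family-wise alpha 0.05).
#' Written to / read from YAML by [runPipeline()]; every field can be
#' overridden from a config file.
#'
#' @return nested list of class `runConfig`.
#' @export
defaultRunConfig <- function() {
  structure(list(
    paths = list(genotypes = NULL, map = NULL, traits = NULL,
                 outdir = "aiopred-run"),
    seed = 1L,
    aio = list(side = 128L),
    dict = list(n_atoms = 16L, block_side = 16L, target_error = 0.01,
                max_sparsity = 10L, max_iter = 30L),
    cnn = list(epochs = 150L, val_split = 0.2, refit_interval = 5L,
               batch_size = 8L, learning_rate = 1e-3, hidden = 64L),
    cv = list(folds = 10L, fixed_control_fraction = NULL),
    attribution = list(alpha = 0.05, side = "greater", top_k = NULL,
                       method = "gradient"),
    simulate = list(n_accessions = 120L, n_snps = 300L,
                    maf_low = 0.05, maf_high = 0.5, n_subpops = 1L,
                    fst = 0, missing_rate = 0, n_causal = 10L,
                    effect_sd = 1, h2 = 0.8, trait_low = 110,
                    trait_high = 440, integer_trait = FALSE)),
    class = "runConfig")
}

.loadRunConfig <- function(config) {
  base <- defaultRunConfig()
  if (is.null(config)) return(base)
  user <- if (is.character(config)) yaml::read_yaml(config) else config
  merge2 <- function(b, u) {
    for (nm in names(u)) {
      b[[nm]] <- if (is.list(b[[nm]]) && is.list(u[[nm]]))
        merge2(b[[nm]], u[[nm]]) else u[[nm]]
    }
    b
  }
  known <- names(base)
  unknown <- setdiff(names(user), known)
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  cfg <- merge2(unclass(base), user)
  stopifnot(cfg$aio$side %% 4 == 0,
            cfg$dict$n_atoms >= 1,
            cfg$cnn$val_split > 0, cfg$cnn$val_split < 1,
            cfg$attribution$alpha > 0, cfg$attribution$alpha < 1,
            cfg$attribution$side %in% c("greater", "two.sided"))
  structure(cfg, class = "runConfig")
}

.manifestAdd <- function(outdir, step, inputs, outputs, seed) {
  mf <- file.path(outdir, "manifest.json")
  old <- if (file.exists(mf)) jsonlite::read_json(mf) else list()
  hash <- function(paths) {
    p <- unlist(paths, use.names = FALSE)
    if (is.null(p) || !length(p)) return(stats::setNames(list(), character(0)))
    p <- p[!is.na(p) & file.exists(p)]
    if (!length(p)) return(stats::setNames(list(), character(0)))
    as.list(tools::md5sum(p))
  }
  old[[step]] <- list(step = step, seed = seed,
                      package = as.character(utils::packageVersion("AIOpred")),
                      inputs = hash(inputs), outputs = hash(outputs))
  jsonlite::write_json(old, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(mf)
}

.cfgObjects <- function(cfg) {
  list(dcfg = dictConfig(nAtoms = cfg$dict$n_atoms,
                         blockSide = cfg$dict$block_side,
                         targetError = cfg$dict$target_error,
                         maxSparsity = cfg$dict$max_sparsity,
                         maxIter = cfg$dict$max_iter, seed = cfg$seed),
       ccfg = cnnConfig(side = cfg$aio$side, epochs = cfg$cnn$epochs,
                        valSplit = cfg$cnn$val_split,
                        refitInterval = cfg$cnn$refit_interval,
                        batchSize = cfg$cnn$batch_size,
                        learningRate = cfg$cnn$learning_rate,
                        hidden = cfg$cnn$hidden, seed = cfg$seed))
}

.loadInputs <- function(cfg) {
  gpath <- cfg$paths$genotypes
  if (is.null(gpath) || !file.exists(gpath))
    stop("genotype file not found; run the 'simulate' step first or point ",
         "paths$genotypes at a VCF/matrix file")
  fmt <- if (grepl("\\.vcf$", gpath, ignore.case = TRUE)) "vcf" else "matrix"
  g <- readGenotypes(gpath, format = fmt, mapFile = cfg$paths$map)
  if (!is.null(cfg$paths$traits)) {
    if (!file.exists(cfg$paths$traits))
      stop("trait file not found: ", cfg$paths$traits)
    traitValues(g, "trait") <- readTraits(cfg$paths$traits)
  }
  g
}

#' Run one pipeline stage end-to-end
#'
#' Subcommands: `"simulate"` writes a synthetic genotype matrix, trait TSV
#' and ground-truth JSON; `"encode"` writes per-accession AIO PNGs;
#' `"learn-dict"` learns and serialises a dictionary; `"train"` runs
#' cross-validation and saves the fold bundles plus a CV report;
#' `"predict"` scores accessions with a saved bundle; `"explain"` computes
#' attention maps, per-SNP importances and the Dunnett selection for a
#' saved bundle.  Every stage appends to `manifest.json` in the output
#' directory (inputs/outputs hashed, seeds, package version), so two runs
#' with the same config and seed are identical.
#'
#' @param subcommand one of simulate, encode, learn-dict, train, predict,
#'   explain.
#' @param config path to a YAML config file, a nested list of overrides, or
#'   `NULL` for the defaults (see [defaultRunConfig()]).
#' @return invisibly, a list of artifact paths.
#' @export
runPipeline <- function(subcommand = c("simulate", "encode", "learn-dict",
                                       "train", "predict", "explain"),
                        config = NULL) {
  subcommand <- match.arg(subcommand)
  cfg <- .loadRunConfig(config)
  outdir <- cfg$paths$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  arts <- switch(subcommand,
                 "simulate" = .stageSimulate(cfg, outdir),
                 "encode" = .stageEncode(cfg, outdir),
                 "learn-dict" = .stageLearnDict(cfg, outdir),
                 "train" = .stageTrain(cfg, outdir),
                 "predict" = .stagePredict(cfg, outdir),
                 "explain" = .stageExplain(cfg, outdir))
  message(sprintf("[aiopred] %s finished in %.1fs -> %s", subcommand,
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  outdir))
  invisible(arts)
}

.stageSimulate <- function(cfg, outdir) {
  s <- cfg$simulate
  g <- simulateGenotypes(s$n_accessions, s$n_snps,
                         mafRange = c(s$maf_low, s$maf_high),
                         nSubpops = s$n_subpops, fst = s$fst,
                         missingRate = s$missing_rate, seed = cfg$seed)
  g <- simulatePhenotype(g, nCausal = s$n_causal, effectSd = s$effect_sd,
                         h2 = s$h2, traitRange = c(s$trait_low, s$trait_high),
                         integerTrait = isTRUE(s$integer_trait),
                         seed = cfg$seed + 1L)
  gp <- file.path(outdir, "genotypes.tsv")
  mp <- file.path(outdir, "snp_map.tsv")
  tp <- file.path(outdir, "traits.tsv")
  jp <- file.path(outdir, "ground_truth.json")
  writeGenotypes(g, gp, mapFile = mp)
  writeTraits(traitValues(g), tp)
  jsonlite::write_json(groundTruth(g), jp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  .manifestAdd(outdir, "simulate", list(), list(gp, mp, tp, jp), cfg$seed)
  list(genotypes = gp, map = mp, traits = tp, groundTruth = jp)
}

.pipelineGenotypes <- function(cfg, outdir) {
  if (is.null(cfg$paths$genotypes)) {
    cfg$paths$genotypes <- file.path(outdir, "genotypes.tsv")
    cfg$paths$map <- file.path(outdir, "snp_map.tsv")
    cfg$paths$traits <- file.path(outdir, "traits.tsv")
  }
  .loadInputs(cfg)
}

.stageEncode <- function(cfg, outdir) {
  g <- .pipelineGenotypes(cfg, outdir)
  aios <- .encodeAll(g, cfg$aio$side)
  dir.create(file.path(outdir, "aio"), showWarnings = FALSE)
  paths <- vapply(aios, function(a)
    writeAIOPng(a, file.path(outdir, "aio", paste0(a@accession, ".png"))),
    character(1))
  .manifestAdd(outdir, "encode", list(cfg$paths$genotypes),
               as.list(paths[1]), cfg$seed)
  list(pngs = unname(paths))
}

.stageLearnDict <- function(cfg, outdir) {
  g <- .pipelineGenotypes(cfg, outdir)
  oc <- .cfgObjects(cfg)
  aios <- .encodeAll(g, cfg$aio$side)
  dict <- learnDictionary(extractBlocks(aios, oc$dcfg$blockSide),
                          nAtoms = oc$dcfg$nAtoms,
                          targetError = oc$dcfg$targetError,
                          maxSparsity = oc$dcfg$maxSparsity,
                          maxIter = oc$dcfg$maxIter, seed = cfg$seed)
  dp <- file.path(outdir, "dictionary.json")
  jsonlite::write_json(list(atoms = dict@atoms, blockSide = dict@blockSide,
                            targetError = dict@targetError,
                            maxSparsity = dict@maxSparsity,
                            trainError = dict@trainError,
                            seed = dict@seed),
                       dp, auto_unbox = TRUE, digits = NA)
  .manifestAdd(outdir, "learn-dict", list(cfg$paths$genotypes), list(dp),
               cfg$seed)
  list(dictionary = dp)
}

.stageTrain <- function(cfg, outdir) {
  g <- .pipelineGenotypes(cfg, outdir)
  oc <- .cfgObjects(cfg)
  fixed <- NULL
  if (!is.null(cfg$cv$fixed_control_fraction)) {
    set.seed(cfg$seed)
    ids <- accessionIds(g)
    fixed <- sample(ids, round(cfg$cv$fixed_control_fraction * length(ids)))
  }
  cv <- trainGenomicModel(g, dcfg = oc$dcfg, ccfg = oc$ccfg,
                          folds = cfg$cv$folds, fixedControl = fixed)
  bp <- file.path(outdir, "bundles.rds.xz")          # serialized S4 bundles
  saveRDS(cv, bp, compress = "xz")
  rp <- file.path(outdir, "cv_report.tsv")
  utils::write.table(cvReport(cv), rp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pp <- file.path(outdir, "cv_predictions.tsv")
  utils::write.table(cv@predictions, pp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .manifestAdd(outdir, "train", list(cfg$paths$genotypes, cfg$paths$traits),
               list(rp, pp), cfg$seed)
  list(bundles = bp, report = rp, predictions = pp)
}

.loadBundles <- function(outdir) {
  bp <- file.path(outdir, "bundles.rds.xz")
  if (!file.exists(bp))
    stop("no trained bundle found in '", outdir,
         "'; run the 'train' subcommand first")
  readRDS(bp)
}

.stagePredict <- function(cfg, outdir) {
  g <- .pipelineGenotypes(cfg, outdir)
  cv <- .loadBundles(outdir)
  best <- cv@bundles[[which.max(cvReport(cv)$control_accuracy)]]
  p <- predictTraits(best, g)
  pp <- file.path(outdir, "predictions.tsv")
  writeTraits(p, pp, traitName = "predicted")
  .manifestAdd(outdir, "predict", list(cfg$paths$genotypes), list(pp),
               cfg$seed)
  list(predictions = pp)
}

.stageExplain <- function(cfg, outdir) {
  g <- .pipelineGenotypes(cfg, outdir)
  cv <- .loadBundles(outdir)
  imp <- snpImportance(cv, g, method = cfg$attribution$method)
  ip <- file.path(outdir, "snp_importance.tsv")
  utils::write.table(data.frame(snp_id = rownames(imp), imp,
                                check.names = FALSE),
                     ip, sep = "\t", quote = FALSE, row.names = FALSE)
  sel <- dunnettSelect(imp, alpha = cfg$attribution$alpha,
                       side = cfg$attribution$side,
                       topK = cfg$attribution$top_k,
                       snpMap = snpMap(g), seed = cfg$seed)
  sp <- file.path(outdir, "selection.tsv")
  bp <- file.path(outdir, "selection.bed")
  exportSelection(sel, tsv = sp, bed = bp)
  tt <- genotypeClassTTest(g, sel@table$snp_id[sel@table$selected])
  tp <- file.path(outdir, "ttests.tsv")
  utils::write.table(tt, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  .manifestAdd(outdir, "explain", list(cfg$paths$genotypes),
               list(ip, sp, tp), cfg$seed)
  list(importance = ip, selection = sp, bed = bp, ttests = tp)
}

#' Out-of-fold per-SNP importance for a cross-validated model
#'
#' Each accession's attention map is computed with the bundle of the fold
#' in which the accession was a *control* sample, so importances are free of
#' training leakage; for a single full-data bundle all accessions use it.
#' Maps are aggregated to per-SNP scores by [aggregateToSnps()].
#'
#' @param cv a [TraitCV-class] or a single [ModelBundle-class].
#' @param gset the [GenotypeSet-class] the model was trained on.
#' @param method attention map variant, see [attentionMap()].
#' @return matrix SNPs x accessions of importance scores.
#' @export
snpImportance <- function(cv, gset, method = "gradient") {
  ids <- accessionIds(gset)
  side <- if (is(cv, "TraitCV")) cv@bundles[[1]]@cnnConfig$side else
    cv@cnnConfig$side
  aios <- .encodeAll(gset, side)
  names(aios) <- ids
  bundleFor <- function(id) {
    if (is(cv, "ModelBundle")) return(cv)
    f <- cv@foldAssignment[match(id, ids)]
    if (is.na(f) || f == 0L || f > length(cv@bundles))
      cv@bundles[[1]] else cv@bundles[[f]]
  }
  featCache <- new.env()
  featsOf <- function(bundle) {
    key <- as.character(bundle@fold)
    if (is.null(featCache[[key]])) {
      bs <- bundle@dictionary@blockSide
      featCache[[key]] <- featureMatrix(
        sparseCode(extractBlocks(aios, bs), bundle@dictionary))
    }
    featCache[[key]]
  }
  maps <- lapply(ids, function(id) {
    b <- bundleFor(id)
    attentionMap(b, aios[[id]], features = featsOf(b)[id, ],
                 method = method)
  })
  aggregateToSnps(maps, nSnps = length(snpMap(gset)$snp_id),
                  snpIds = snpMap(gset)$snp_id)
}
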