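# End-to-end orchestration: simulate -> digest -> search -> assemble ->
# tree/network, as one reproducible, seeded run with stable file names.

#' Default run configuration
#'
#' Assembles the full pipeline configuration. All randomness flows from the
#' single root \code{seed} through named per-stage substreams, so a config
#' determines every output byte.
#'
#' @param seed Root seed.
#' @param sim A \code{\link{simulationConfig}}; its own seed is overridden
#'   by \code{seed}.
#' @param tolerance MS and MS/MS match tolerance in Da (default 0.5).
#' @param ionScoreThreshold PSM acceptance threshold (default 40).
#' @param maxMissed Maximum missed cleavages in the search database
#'   (default 2).
#' @param maxVariable Maximum variable-modification instances per peptide
#'   (default 2).
#' @param fillMode Fill for unobserved fossil sites in the phylogenetic
#'   alignment: \code{"unknown"} (missing data; default) or
#'   \code{"consensus"}.
#' @param minPeptideLength Shortest fossil peptide fragmented by MS/MS
#'   (default 6).
#' @param precursorWindow MH+ range (Da) of peptides selected for MS/MS
#'   (default c(800, 3500): precursors are picked from the MALDI PMF
#'   window, as is standard when fragmenting fingerprint peaks).
#' @param gammaCategories,pInv Rate-heterogeneity settings for ML
#'   (defaults 4 and 0).
#' @param bootstrapReplicates Bootstrap replicates (default 100; 0 skips
#'   bootstrapping).
#' @param sisterTaxon Putative sister of the fossil, for the monophyly
#'   report (default "tenrec").
#' @param outgroup Rooting taxon (default "outgroup").
#' @param spectraDir Optional directory of MGF files replacing the
#'   simulated fossil spectra.
#' @return List of class \code{"RunConfig"}.
#' @export
defaultRunConfig <- function(seed = 1L, sim = simulationConfig(seed = seed),
                             tolerance = 0.5, ionScoreThreshold = 40,
                             maxMissed = 2L, maxVariable = 2L,
                             fillMode = "unknown", minPeptideLength = 6L,
                             precursorWindow = c(800, 3500),
                             gammaCategories = 4L, pInv = 0,
                             bootstrapReplicates = 100L,
                             sisterTaxon = "tenrec", outgroup = "outgroup",
                             spectraDir = NULL) {
  stopifnot(tolerance > 0, ionScoreThreshold >= 0, maxMissed >= 0,
            maxVariable >= 0)
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), sim = sim, tolerance = tolerance,
                 ionScoreThreshold = ionScoreThreshold,
                 maxMissed = as.integer(maxMissed),
                 maxVariable = as.integer(maxVariable),
                 fillMode = match.arg(fillMode, c("unknown", "consensus")),
                 minPeptideLength = as.integer(minPeptideLength),
                 precursorWindow = precursorWindow,
                 gammaCategories = as.integer(gammaCategories), pInv = pInv,
                 bootstrapReplicates = as.integer(bootstrapReplicates),
                 sisterTaxon = sisterTaxon, outgroup = outgroup,
                 spectraDir = spectraDir),
            class = "RunConfig")
}

#' Read a run configuration from a YAML file
#'
#' Recognised keys mirror the arguments of \code{\link{defaultRunConfig}}
#' and \code{\link{simulationConfig}} (the latter nested under \code{sim};
#' \code{sim$tree} may be a Newick string or a file path). Unknown keys are
#' rejected.
#'
#' @param file YAML path.
#' @return List of class \code{"RunConfig"}.
#' @export
readRunConfig <- function(file) {
  raw <- yaml::read_yaml(file)
  simRaw <- raw$sim
  raw$sim <- NULL
  known <- setdiff(names(formals(defaultRunConfig)), c("sim"))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  simArgs <- list()
  if (!is.null(simRaw)) {
    if (!is.null(simRaw$tree)) {
      simRaw$tree <- if (file.exists(simRaw$tree))
        ape::read.tree(simRaw$tree) else ape::read.tree(text = simRaw$tree)
    }
    if (!is.null(simRaw$chainLengths))
      simRaw$chainLengths <- as.integer(simRaw$chainLengths)
    badS <- setdiff(names(simRaw), names(formals(simulationConfig)))
    if (length(badS))
      stop("unknown sim config keys: ", paste(badS, collapse = ", "))
    simArgs <- simRaw
  }
  if (!is.null(raw$seed)) simArgs$seed <- raw$seed
  cfg <- do.call(defaultRunConfig,
                 c(raw, list(sim = do.call(simulationConfig, simArgs))))
  cfg
}

.logLine <- function(log, ...) {
  line <- paste0(...)
  cat(line, "\n", file = log, append = TRUE, sep = "")
  message(line)
}

#' Run the full pipeline
#'
#' Executes simulate -> spectra -> database -> search -> assemble ->
#' phylogenetics and writes every stage's outputs under \code{outDir} with
#' stable file names (sequences, peak lists, MGF, PSM and coverage tables,
#' alignment, PHYLIP distances, Newick tree, NEXUS splits, monophyly
#' report, log). A stage failure aborts with the stage name and leaves a
#' \code{FAILED} marker next to the partial outputs.
#'
#' @param config A \code{"RunConfig"} from \code{\link{defaultRunConfig}}
#'   or \code{\link{readRunConfig}}.
#' @param outDir Output directory (created if needed).
#' @return Invisible list with the main in-memory results: \code{alignment},
#'   \code{psms}, \code{coverage}, \code{tree} (with bootstrap supports when
#'   requested), \code{network}, \code{monophyly}, \code{cladeSupport} and
#'   \code{mlFit}; the PMF similarity matrix and all tables are on disk
#'   under \code{outDir}.
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(outDir, "run.log")
  cat("", file = log)
  failed <- file.path(outDir, "FAILED")
  if (file.exists(failed)) unlink(failed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)), failed)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  cfg <- config
  sim <- cfg$sim
  seed <- cfg$seed
  .logLine(log, "seed: ", seed)
  .logLine(log, "tree: ", ape::write.tree(sim$tree))
  .logLine(log, "tolerance: ", cfg$tolerance, "  ion score threshold: ",
           cfg$ionScoreThreshold, "  max missed: ", cfg$maxMissed,
           "  max variable mods: ", cfg$maxVariable)

  ## -- simulate ------------------------------------------------------
  res <- stage("simulate", {
    l1 <- sim$chainLengths[1]; l2 <- sim$chainLengths[2]
    root <- list(
      alpha1 = simulateReference(deriveSeed(seed, 101), l1,
                                 sim$prolineFreq, sim$krFreq),
      alpha2 = simulateReference(deriveSeed(seed, 102), l2,
                                 sim$prolineFreq, sim$krFreq))
    leaves <- evolveSequences(root, sim$tree, deriveSeed(seed, 103),
                              sim$gInvariant)
    fossilTrue <- leaves[[sim$fossilTaxon]]
    extant <- leaves[names(leaves) != sim$fossilTaxon]
    degraded <- degradeToFossil(fossilTrue, sim$targetCoverage,
                                deriveSeed(seed, 104))
    .logLine(log, "simulated ", length(leaves), " taxa; fossil block ",
             "retention ", sprintf("%.3f", degraded$coverage))
    dir.create(file.path(outDir, "sequences"), showWarnings = FALSE)
    writeAlignedFasta(vapply(extant, `[[`, "", "alpha1"),
                      file.path(outDir, "sequences", "extant_alpha1.fasta"))
    writeAlignedFasta(vapply(extant, `[[`, "", "alpha2"),
                      file.path(outDir, "sequences", "extant_alpha2.fasta"))
    writeAlignedFasta(
      c(structure(fossilTrue$alpha1, names = "fossil_truth_alpha1"),
        structure(fossilTrue$alpha2, names = "fossil_truth_alpha2")),
      file.path(outDir, "sequences", "fossil_truth.fasta"))
    list(root = root, leaves = leaves, extant = extant,
         fossilTrue = fossilTrue, degraded = degraded)
  })

  ## -- spectra -------------------------------------------------------
  spectraRes <- stage("spectra", {
    dir.create(file.path(outDir, "spectra"), showWarnings = FALSE)
    blocks <- res$degraded$retained
    blocks <- blocks[blocks$end - blocks$start + 1L >=
                       cfg$minPeptideLength, , drop = FALSE]
    spectra <- vector("list", nrow(blocks))
    for (i in seq_len(nrow(blocks))) {
      ch <- blocks$chain[i]
      pep <- substr(res$fossilTrue[[ch]], blocks$start[i], blocks$end[i])
      mods <- assignHydroxylations(pep, blocks$start[i],
                                   sim$hydroxylationRate,
                                   deriveSeed(seed, 2000 + i))
      mh <- peptideMass(pep, mods)[["mhplus"]]
      # precursors are selected from the MALDI window
      if (mh < cfg$precursorWindow[1] || mh > cfg$precursorWindow[2]) next
      spectra[[i]] <- simulateMsms(
        pep, mods, seed = deriveSeed(seed, 3000 + i),
        ionCounts = sim$msmsIonCounts, dropout = sim$msmsNoise$dropout,
        noisePeaks = sim$msmsNoise$noisePeaks,
        jitterSd = sim$msmsNoise$jitterSd,
        label = paste0("fossil_", ch, "_", blocks$start[i], "-",
                       blocks$end[i]))
    }
    spectra <- Filter(Negate(is.null), spectra)
    if (length(spectra))
      writeMgf(spectra, file.path(outDir, "spectra", "fossil_msms.mgf"))
    # PMFs: fossil from retained peptides, extant from their digests
    pmfs <- list()
    k <- 0L
    for (tx in names(res$leaves)) {
      k <- k + 1L
      if (tx == sim$fossilTaxon) {
        mh <- vapply(seq_len(nrow(blocks)), function(i)
          peptideMass(substr(res$fossilTrue[[blocks$chain[i]]],
                             blocks$start[i], blocks$end[i]))[["mhplus"]],
          1)
      } else {
        dg <- rbind(digestVariants(res$leaves[[tx]]$alpha1, "alpha1",
                                   maxMissed = 0L, maxVariable = 1L),
                    digestVariants(res$leaves[[tx]]$alpha2, "alpha2",
                                   maxMissed = 0L, maxVariable = 1L))
        mh <- dg$mhplus
      }
      mh <- mh[mh >= 800 & mh <= 3500]
      pmfs[[tx]] <- simulatePmf(mh, sim$pmfNoise$jitterSd,
                                sim$pmfNoise$decoys,
                                seed = deriveSeed(seed, 4000 + k),
                                label = tx)
      writePeakList(pmfs[[tx]],
                    file.path(outDir, "spectra", paste0("pmf_", tx, ".tsv")))
    }
    simMat <- outer(names(pmfs), names(pmfs), Vectorize(function(i, j)
      pmfSimilarity(pmfs[[i]], pmfs[[j]], cfg$tolerance)))
    dimnames(simMat) <- list(names(pmfs), names(pmfs))
    utils::write.table(round(simMat, 4),
                       file.path(outDir, "pmf_similarity.tsv"),
                       sep = "\t", quote = FALSE)
    spectra
  })

  ## -- database ------------------------------------------------------
  db <- stage("database", {
    cons <- list(
      alpha1 = consensusSequence(vapply(res$extant, `[[`, "", "alpha1")),
      alpha2 = consensusSequence(vapply(res$extant, `[[`, "", "alpha2")))
    consFilled <- lapply(cons, function(s) {
      # consensus ties ('?') cannot enter a searchable sequence: drop those
      # peptides by leaving '?' (digestVariants flags them unobservable)
      s
    })
    consensusDb <- rbind(
      cbind(taxon = "consensus",
            digestVariants(consFilled$alpha1, "alpha1", cfg$maxMissed,
                           cfg$maxVariable)),
      cbind(taxon = "consensus",
            digestVariants(consFilled$alpha2, "alpha2", cfg$maxMissed,
                           cfg$maxVariable)))
    extantDb <- do.call(rbind, lapply(names(res$extant), function(tx)
      rbind(cbind(taxon = tx,
                  digestVariants(res$extant[[tx]]$alpha1, "alpha1",
                                 cfg$maxMissed, cfg$maxVariable)),
            cbind(taxon = tx,
                  digestVariants(res$extant[[tx]]$alpha2, "alpha2",
                                 cfg$maxMissed, cfg$maxVariable)))))
    .logLine(log, "database: ", nrow(consensusDb), " consensus variants + ",
             nrow(extantDb), " extant variants")
    list(consensus = cons, consensusDb = consensusDb, extantDb = extantDb)
  })

  ## -- search --------------------------------------------------------
  psms <- stage("search", {
    spectra <- spectraRes
    if (!is.null(cfg$spectraDir)) {
      files <- list.files(cfg$spectraDir, pattern = "\\.mgf$",
                          full.names = TRUE)
      spectra <- unlist(lapply(files, readMgf), recursive = FALSE)
    }
    if (!length(spectra))
      stop("no MS/MS spectra to search")
    psms <- searchSpectra(spectra,
                          database = rbind(db$consensusDb, db$extantDb),
                          tol = cfg$tolerance,
                          threshold = cfg$ionScoreThreshold,
                          mode = "error_tolerant",
                          etDatabase = db$consensusDb)
    writePsmTable(psms, file.path(outDir, "psms.tsv"))
    .logLine(log, "search: ", nrow(psms), " PSMs, ",
             sum(psms$accepted), " accepted at ion score > ",
             cfg$ionScoreThreshold)
    psms
  })

  ## -- assemble ------------------------------------------------------
  asm <- stage("assemble", {
    masterLengths <- c(alpha1 = sim$chainLengths[1],
                       alpha2 = sim$chainLengths[2])
    calls <- mapPsmsToSites(psms, masterLengths)
    fossilChains <- lapply(c("alpha1", "alpha2"), function(ch)
      buildTaxonSequence(calls[calls$chain == ch, , drop = FALSE],
                         references = vapply(res$extant, `[[`, "", ch),
                         masterLength = masterLengths[[ch]],
                         fillMode = cfg$fillMode))
    names(fossilChains) <- c("alpha1", "alpha2")
    a1 <- c(vapply(res$extant, `[[`, "", "alpha1"),
            structure(fossilChains$alpha1, names = sim$fossilTaxon))
    a2 <- c(vapply(res$extant, `[[`, "", "alpha2"),
            structure(fossilChains$alpha2, names = sim$fossilTaxon))
    aln <- resolveIsobaric(concatenateChains(a1, a2))
    writeAlignedFasta(aln, file.path(outDir, "alignment.fasta"))
    cov <- coverageReport(aln, file.path(outDir, "coverage.tsv"))
    .logLine(log, "assemble: fossil coverage ",
             sprintf("%.3f", cov$coverage[cov$taxon == sim$fossilTaxon]))
    list(alignment = aln, coverage = cov)
  })

  ## -- phylogenetics -------------------------------------------------
  phy <- stage("phylo", {
    d <- mlDistances(asm$alignment)
    writeDistPhylip(d, file.path(outDir, "distances.phy"))
    fit <- mlTree(asm$alignment, k = cfg$gammaCategories,
                  pInv = cfg$pInv)
    tree <- fit$tree
    if (cfg$bootstrapReplicates > 0) {
      tree <- bootstrapSupport(fit, cfg$bootstrapReplicates,
                               seed = deriveSeed(seed, 301))
    }
    ape::write.tree(tree, file.path(outDir, "tree.nwk"))
    net <- splitNetwork(d)
    writeSplitsNexus(net, file.path(outDir, "network.nex"))
    mono <- checkMonophyly(tree, c(sim$fossilTaxon, cfg$sisterTaxon),
                           cfg$outgroup)
    sup <- if (cfg$bootstrapReplicates > 0)
      cladeSupport(tree, c(sim$fossilTaxon, cfg$sisterTaxon), cfg$outgroup)
    else NA_real_
    writeLines(c(
      paste0("taxa: ", sim$fossilTaxon, ", ", cfg$sisterTaxon),
      paste0("monophyletic: ", mono$monophyletic),
      paste0("smallest containing clade: ",
             paste(mono$clade, collapse = ", ")),
      paste0("bootstrap support: ", sup)),
      file.path(outDir, "monophyly.txt"))
    .logLine(log, "phylo: logLik ", sprintf("%.2f", fit$logLik),
             ", fossil+", cfg$sisterTaxon, " monophyletic: ",
             mono$monophyletic, ", support: ", sup)
    list(tree = tree, network = net, monophyly = mono, support = sup,
         mlFit = fit)
  })

  invisible(list(alignment = asm$alignment, psms = psms,
                 coverage = asm$coverage, tree = phy$tree,
                 network = phy$network, monophyly = phy$monophyly,
                 cladeSupport = phy$support, mlFit = phy$mlFit))
}
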