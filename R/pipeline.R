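# End-to-end orchestration: one configuration object drives the simulator,
# the parental phasing workup, and the per-embryo integrated analysis.

#' Default pipeline configuration
#'
#' Returns the full parameter set of the pipeline with its default study
#' conditions: a 5 Mb phasing region with 400 markers and a central
#' pathogenic target, nine 40 Mb background chromosomes with 1000 markers
#' each, linked-read fragments of mean 40 kb at 25x molecule coverage with
#' 2% allele error, MDA genotyping at depth 30 with 10% allele dropout, and
#' 1 Mb window counts (mean 100, NB dispersion 0.05) against a 20-sample
#' diploid reference panel.
#'
#' @param family `"AD"` (maternal carrier), `"AR"` (both parents carry the
#'   same variant) or `"compound"` (a different pathogenic allele on each
#'   parent).
#' @return Nested list of parameters; every entry can be overridden via
#'   [readConfig()] or [utils::modifyList()].
#' @export
defaultConfig <- function(family = c("AD", "AR", "compound")) {
  family <- match.arg(family)
  list(
    family = family,
    region = list(chrom = "chr1", start = 1, end = 5e6, nMarkers = 800,
                  mafRange = c(0.2, 0.5), targetPos = 2.5e6),
    genome = list(nChroms = 9, chromLength = 4e7, markersPerChrom = 1000,
                  mafRange = c(0.1, 0.5)),
    fragments = list(coverage = 25, lenMean = 4e4, lenSd = 4e4,
                     perSiteError = 0.02, minQuality = 0, minSites = 2,
                     minSpanReads = 5, minConsistency = 0.8, windowBp = 2e6),
    genotyping = list(meanDepth = 30, adoRate = 0.10, perReadError = 0.01,
                      callError = 0),
    windows = list(width = 1e6, meanCount = 100, dispersion = 0.05,
                   nReference = 20),
    cnv = list(alpha = 0.01, nPerm = 1000, minWidth = 3, mergeTol = 0.1,
               bands = c(0.2, 0.8), minRefCount = 10),
    ploidy = list(depthFloor = 8, minCallable = 50, threshold = 3,
                  genomeFrac = 0.8),
    roh = list(depthFloor = 8, minSites = 20, threshold = -1),
    linkage = list(minRun = 3, minFlankVotes = 3, maxMendelRate = 0.1),
    embryos = list(
      list(id = "E1", ploidy = "diploid",
           transmit = list(maternal = "nonrisk", paternal = "nonrisk")),
      list(id = "E2", ploidy = "diploid",
           transmit = list(maternal = "nonrisk", paternal = "nonrisk"),
           crossovers = list(parent = "maternal", chrom = "chr1", pos = 1.2e6)),
      list(id = "E3", ploidy = "diploid",
           transmit = list(maternal = "risk", paternal = "risk")),
      list(id = "E4", ploidy = "trisomy", chrom = "chr4",
           transmit = list(maternal = "nonrisk", paternal = "nonrisk")),
      list(id = "E5", ploidy = "monosomy", chrom = "chr9",
           mosaicFraction = 0.30,
           transmit = list(maternal = "risk", paternal = "nonrisk")),
      list(id = "E6", ploidy = "diploid",
           roh = list(chrom = "chr5", start = 1e7, end = 1.3e7),
           transmit = list(maternal = "nonrisk", paternal = "nonrisk")),
      list(id = "E7", ploidy = "segmental", chrom = "chr9",
           segStart = 1e7, segEnd = 2e7, segDirection = "gain",
           transmit = list(maternal = "nonrisk", paternal = "risk")),
      list(id = "E8", ploidy = "triploid",
           transmit = list(maternal = "risk", paternal = "risk"))))
}

#' Read a YAML configuration, merged over the defaults
#'
#' @param path YAML file with any subset of the [defaultConfig()] keys.
#' @return The merged configuration list.
#' @export
readConfig <- function(path) {
  user <- yaml::read_yaml(path)
  base <- defaultConfig(if (!is.null(user$family)) user$family else "AD")
  cfg <- utils::modifyList(base, user)
  if (!is.null(user$embryos)) cfg$embryos <- user$embryos
  cfg
}

configHash <- function(config) {
  fnv1a(as.character(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)))
}

# target specification implied by the configured family structure
configTarget <- function(config) {
  r <- config$region
  switch(config$family,
    AD = pathogenicTarget(r$chrom, r$targetPos, "A", "T",
                          parent = "maternal", inheritance = "AD"),
    AR = pathogenicTarget(r$chrom, r$targetPos, "A", "T",
                          parent = "maternal", inheritance = "AR",
                          partner = data.frame(chrom = r$chrom,
                                               pos = r$targetPos,
                                               ref = "A", alt = "T")),
    compound = pathogenicTarget(r$chrom, r$targetPos, "A", "T",
                                parent = "maternal", inheritance = "AR",
                                partner = data.frame(chrom = r$chrom,
                                                     pos = r$targetPos + 207,
                                                     ref = "C", alt = "G")))
}

# genome-wide marker map from a configuration
configMap <- function(config, seeds) {
  r <- config$region
  g <- config$genome
  fine <- buildMarkerMap(r$chrom, r$start, r$end, r$nMarkers,
                         mafRange = r$mafRange, target = configTarget(config),
                         seed = seeds[1])
  maps <- list(fine)
  for (k in seq_len(g$nChroms))
    maps[[k + 1L]] <- buildMarkerMap(sprintf("chr%d", k + 1L), 1,
                                     g$chromLength, g$markersPerChrom,
                                     mafRange = g$mafRange,
                                     seed = seeds[k + 1L])
  combineMarkerMaps(maps)
}

# phase and sign one carrier parent from fragment evidence
phaseParent <- function(truth, parent, config, seed) {
  cfgF <- config$fragments
  map <- truthMap(truth)
  r <- config$region
  nFrag <- ceiling(cfgF$coverage * (r$end - r$start + 1) / cfgF$lenMean)
  frags <- simulateFragments(truth, parent = parent, nFragments = nFrag,
                             fragLenMean = cfgF$lenMean,
                             fragLenSd = cfgF$lenSd,
                             perSiteError = cfgF$perSiteError,
                             seed = seed, chrom = r$chrom)
  geno <- truthGenotypes(truth)[[parent]]
  s <- markerSites(map)
  hetFine <- which(isHetGt(geno) & s$chrom == r$chrom)
  filtered <- filterFragments(frags, hetSites = hetFine,
                              minSites = cfgF$minSites,
                              minQuality = cfgF$minQuality)
  phased <- phaseSites(filtered, hetFine)
  ct <- carrierTable(map)
  tIdx <- ct$site[ct$parent == parent][1]
  signed <- signHaplotypes(phased, filtered, map,
                           carrierGenotype = geno[tIdx], parent = parent,
                           targetSite = tIdx,
                           minSpanReads = cfgF$minSpanReads,
                           minConsistency = cfgF$minConsistency)
  other <- if (parent == "maternal") "paternal" else "maternal"
  if (signingCall(signed) == "signed")
    signed <- suppressWarnings(
      selectInformativeSnps(signed, truthGenotypes(truth)[[other]], map,
                            windowBp = cfgF$windowBp))
  list(signed = signed, fragments = frags)
}

# build one embryo truth from its config entry
configEmbryoTruth <- function(truth, e, seed) {
  co <- if (!is.null(e$crossovers)) as.data.frame(e$crossovers) else NULL
  roh <- if (!is.null(e$roh)) as.data.frame(e$roh) else NULL
  simulateEmbryo(truth, crossovers = co,
                 ploidy = if (!is.null(e$ploidy)) e$ploidy else "diploid",
                 chrom = if (!is.null(e$chrom)) e$chrom else NA_character_,
                 segStart = if (!is.null(e$segStart)) e$segStart else NA_real_,
                 segEnd = if (!is.null(e$segEnd)) e$segEnd else NA_real_,
                 segDirection = if (!is.null(e$segDirection)) e$segDirection else "gain",
                 mosaicFraction = if (!is.null(e$mosaicFraction)) e$mosaicFraction else 1,
                 rohRegions = roh, transmit = e$transmit, seed = seed)
}

#' Run the full integrated PGT pipeline on simulated data
#'
#' Simulates the family (marker map, phased parental truth, linked-read
#' fragments), performs the preclinical workup (phasing, signing,
#' informative-SNP selection) for every carrier parent, simulates the
#' reference panels, and produces the integrated report (linkage + CNV +
#' ploidy + ROH) for every configured embryo.
#'
#' @param config Configuration list (see [defaultConfig()]).
#' @param seed Master integer seed; all randomness derives from it.
#' @param outDir Optional output directory; when given, every artifact is
#'   written (parental VCF, fragment TSVs, signed-haplotype JSONs, embryo
#'   VCFs, window-count TSVs, per-embryo report JSONs, segment and ROH BED
#'   files, cohort TSV).
#' @return Invisibly, a list with `map`, `truth`, `signed` (per carrier
#'   parent), `panel`, `reports` (list of [EmbryoReport-class]) and
#'   `cohort` (data.frame).
#' @export
runEndToEnd <- function(config = defaultConfig(), seed = 1L, outDir = NULL) {
  nEmb <- length(config$embryos)
  nRef <- config$windows$nReference
  nChrom <- config$genome$nChroms + 1L
  seeds <- deriveSeeds(seed, nChrom + 3L + 2L * nRef + 4L * nEmb)
  mapSeeds <- seeds[seq_len(nChrom)]
  at <- nChrom
  truthSeed <- seeds[at + 1L]
  fragSeeds <- seeds[at + 2:3]
  at <- at + 3L
  panelSeeds <- matrix(seeds[at + seq_len(2L * nRef)], nrow = 2L)
  at <- at + 2L * nRef
  embSeeds <- matrix(seeds[at + seq_len(4L * nEmb)], nrow = 4L)

  map <- configMap(config, mapSeeds)
  truth <- makeParentalTruth(map, seed = truthSeed)
  target <- targetSpec(map)
  carriers <- unique(carrierTable(map)$parent)
  signed <- list()
  frags <- list()
  for (k in seq_along(carriers)) {
    res <- phaseParent(truth, carriers[k], config, seed = fragSeeds[k])
    signed[[carriers[k]]] <- res$signed
    frags[[carriers[k]]] <- res$fragments
  }

  # reference panels: genotype panel for ploidy/ROH, count panel is built
  # per embryo by the window-count generator
  g <- config$genotyping
  panel <- lapply(seq_len(nRef), function(k) {
    et <- simulateEmbryo(truth, ploidy = "diploid", seed = panelSeeds[1, k])
    simulateEmbryoGenotypes(et, truth, meanDepth = g$meanDepth,
                            adoRate = g$adoRate,
                            perReadError = g$perReadError,
                            callError = g$callError,
                            embryoId = sprintf("REF%02d", k),
                            seed = panelSeeds[2, k])
  })
  pStats <- panelStats(panel, depthFloor = config$ploidy$depthFloor,
                       minCallable = config$ploidy$minCallable)
  windows <- makeWindows(map, config$windows$width)
  f2 <- panelHetFraction(panel, windows, depthFloor = config$roh$depthFloor,
                         minSites = config$roh$minSites)

  prov <- list(seed = seed, configHash = configHash(config))
  reports <- list()
  embryos <- list()
  for (k in seq_len(nEmb)) {
    e <- config$embryos[[k]]
    et <- configEmbryoTruth(truth, e, seed = embSeeds[1, k])
    eg <- simulateEmbryoGenotypes(et, truth, meanDepth = g$meanDepth,
                                  adoRate = g$adoRate,
                                  perReadError = g$perReadError,
                                  callError = g$callError,
                                  embryoId = e$id, seed = embSeeds[2, k])
    wc <- simulateWindowCounts(et, windowWidth = config$windows$width,
                               meanCount = config$windows$meanCount,
                               dispersion = config$windows$dispersion,
                               nReference = nRef, seed = embSeeds[3, k])
    cfgC <- config$cnv
    cnv <- runCnv(wc, alpha = cfgC$alpha, nPerm = cfgC$nPerm,
                  minWidth = cfgC$minWidth, mergeTol = cfgC$mergeTol,
                  bands = cfgC$bands, minRefCount = cfgC$minRefCount,
                  seed = embSeeds[4, k])
    st <- chromStats(eg, depthFloor = config$ploidy$depthFloor,
                     minCallable = config$ploidy$minCallable)
    pl <- zScores(st, pStats, threshold = config$ploidy$threshold,
                  genomeFrac = config$ploidy$genomeFrac)
    f1 <- windowHetFraction(eg, windows, depthFloor = config$roh$depthFloor,
                            minSites = config$roh$minSites)
    roh <- rohCalls(f1, f2, cnvSegments(cnv),
                    threshold = config$roh$threshold)
    lk <- runLinkage(eg, signed, target,
                     ploidyAbnormal = ploidyCall(pl) != "normal",
                     minRun = config$linkage$minRun,
                     minFlankVotes = config$linkage$minFlankVotes,
                     maxMendelRate = config$linkage$maxMendelRate)
    reports[[e$id]] <- compileEmbryoReport(e$id, lk, cnv, pl, roh,
                                           provenance = prov)
    embryos[[e$id]] <- list(truth = et, genotypes = eg, windowCounts = wc)
  }
  cohort <- cohortTable(reports)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeParentalVcf(truth, file.path(outDir, "parents.vcf"))
    for (p in names(signed)) {
      writeFragmentsTsv(frags[[p]], file.path(outDir, sprintf("fragments_%s.tsv", p)))
      writeSignedJson(signed[[p]], file.path(outDir, sprintf("signed_%s.json", p)))
    }
    pdir <- file.path(outDir, "panel")
    dir.create(pdir, showWarnings = FALSE)
    for (pg in panel) writeEmbryoVcf(pg, file.path(pdir, paste0(embryoId(pg), ".vcf")))
    for (id in names(reports)) {
      writeEmbryoVcf(embryos[[id]]$genotypes, file.path(outDir, paste0(id, ".vcf")))
      writeWindowCountsTsv(embryos[[id]]$windowCounts,
                           file.path(outDir, paste0(id, "_windows.tsv")))
      writeSegmentsBed(reports[[id]]@cnv, file.path(outDir, paste0(id, "_cnv.bed")))
      writeRohBed(reports[[id]]@roh, file.path(outDir, paste0(id, "_roh.bed")))
      writeEmbryoReport(reports[[id]], file.path(outDir, paste0(id, "_report.json")))
    }
    writeCohortTsv(reports, file.path(outDir, "cohort.tsv"))
  }
  invisible(list(map = map, truth = truth, signed = signed, panel = panel,
                 reports = reports, cohort = cohort))
}
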