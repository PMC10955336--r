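# Shared fixtures, all built in code.

# a FragmentSet from a list of observation vectors; each element is a named
# integer vector site -> allele
tinyFragments <- function(obsList, nSites = max(unlist(lapply(obsList, function(x)
  as.integer(names(x))))), quals = NULL, chrom = "chr1",
  starts = NULL, ends = NULL) {
  obs <- do.call(rbind, lapply(seq_along(obsList), function(f) {
    x <- obsList[[f]]
    data.frame(fragment = f, site = as.integer(names(x)),
               allele = as.integer(x),
               qual = if (is.null(quals)) 60 else quals[[f]])
  }))
  if (is.null(obs))
    obs <- data.frame(fragment = integer(0), site = integer(0),
                      allele = integer(0), qual = numeric(0))
  n <- length(obsList)
  if (n == 0L)
    return(new("FragmentSet", parent = "maternal",
               fragments = data.frame(barcode = character(0),
                                      chrom = character(0), start = numeric(0),
                                      end = numeric(0), hap = integer(0)),
               observations = obs, nSites = as.integer(nSites)))
  new("FragmentSet", parent = "maternal",
      fragments = data.frame(barcode = sprintf("BX%03d", seq_len(n)),
                             chrom = chrom,
                             start = if (is.null(starts)) rep(0, n) else starts,
                             end = if (is.null(ends)) rep(1e6, n) else ends,
                             hap = NA_integer_),
      observations = obs, nSites = as.integer(nSites))
}

# exhaustive minimum-MEC over all 2^(n-1) phase assignments of the observed
# sites; independent of the greedy phaser
bruteForceMEC <- function(fragments, sites) {
  ob <- fragmentObservations(fragments)
  ob <- ob[ob$site %in% sites, , drop = FALSE]
  sites <- sort(unique(ob$site))
  n <- length(sites)
  X <- matrix(NA_integer_, nrow = max(ob$fragment), ncol = n)
  X[cbind(ob$fragment, match(ob$site, sites))] <- ob$allele
  A <- !is.na(X)
  X0 <- X; X0[!A] <- 0L
  best <- Inf
  for (code in 0:(2^(n - 1) - 1)) {
    h <- c(0L, as.integer(intToBits(code))[seq_len(n - 1)])
    mism <- rowSums(A * (X0 != matrix(h, nrow(X), n, byrow = TRUE)))
    k <- rowSums(A)
    best <- min(best, sum(pmin(mism, k - mism)))
  }
  best
}

# small seeded family on one region, cached per test session
familyFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tg <- pathogenicTarget("chr1", 2.5e6, "A", "T", parent = "maternal",
                             inheritance = "AD")
      map <- buildMarkerMap("chr1", 1, 5e6, nMarkers = 800, target = tg,
                            seed = 7)
      truth <- makeParentalTruth(map, seed = 3, hetIn = "maternal")
      geno <- truthGenotypes(truth)$maternal
      het <- which(markerSites(map)$pos > 0 &
                   substr(geno, 1, 1) != substr(geno, 3, 3))
      frags <- filterFragments(
        simulateFragments(truth, "maternal", nFragments = 3125, seed = 5),
        hetSites = het)
      phased <- phaseSites(frags, het)
      tIdx <- targetIndices(map)[1]
      signed <- signHaplotypes(phased, frags, map,
                               carrierGenotype = geno[tIdx],
                               parent = "maternal", targetSite = tIdx)
      signed <- suppressWarnings(selectInformativeSnps(
        signed, truthGenotypes(truth)$paternal, map))
      cache <<- list(target = tg, map = map, truth = truth, het = het,
                     frags = frags, phased = phased, signed = signed,
                     tIdx = tIdx)
    }
    cache
  }
})

# dense single-chromosome fixture for windowed-heterozygosity analyses
rohFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      map <- buildMarkerMap("chr5", 1, 1e7, 1200, seed = 31,
                            mafRange = c(0.2, 0.5))
      truth <- makeParentalTruth(map, seed = 32)
      panel <- lapply(1:12, function(k)
        simulateEmbryoGenotypes(simulateEmbryo(truth, seed = 330 + k), truth,
                                embryoId = sprintf("P%d", k), seed = 350 + k))
      windows <- makeWindows(map, 1e6)
      cache <<- list(map = map, truth = truth, panel = panel,
                     windows = windows,
                     f2 = panelHetFraction(panel, windows))
    }
    cache
  }
})

# 5-chromosome genome fixture for the PGT-A channels
genomeFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      maps <- lapply(1:5, function(k)
        buildMarkerMap(sprintf("chr%d", k), 1, 4e7, 200, seed = k,
                       mafRange = c(0.1, 0.5)))
      map <- combineMarkerMaps(maps)
      truth <- makeParentalTruth(map, seed = 11)
      cache <<- list(map = map, truth = truth)
    }
    cache
  }
})
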