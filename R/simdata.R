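# Synthetic-data engine: seeded generators for every input the analysis
# modules consume (marker maps, phased parental truth, barcoded linked-read
# fragments, MDA-style embryo genotypes, window read counts). All generators
# are deterministic for a fixed seed and restore the caller's RNG state.

#' Construct a pathogenic target specification
#'
#' @param chrom,pos,ref,alt Primary pathogenic variant (1-based position).
#' @param varType `"SNV"`, `"INS"` or `"DEL"`.
#' @param parent Carrier of the primary variant: `"maternal"` or `"paternal"`.
#' @param inheritance `"AD"` or `"AR"`.
#' @param partner Optional one-row data.frame (`chrom`, `pos`, `ref`, `alt`,
#'   `var_type`) for a pathogenic allele carried by the other parent: the
#'   same variant for classic autosomal-recessive families, a different one
#'   for compound heterozygosity. Requires `inheritance = "AR"`.
#' @return A [PathogenicTarget-class].
#' @examples
#' pathogenicTarget("chr11", 5248200, "A", "T", parent = "paternal",
#'                  inheritance = "AR")
#' @export
pathogenicTarget <- function(chrom, pos, ref, alt, varType = "SNV",
                             parent = "maternal", inheritance = "AD",
                             partner = NULL) {
  site <- data.frame(chrom = chrom, pos = as.numeric(pos), ref = ref,
                     alt = alt, var_type = varType,
                     stringsAsFactors = FALSE)
  if (is.null(partner))
    partner <- site[0, ]
  else {
    if (!"var_type" %in% names(partner)) partner$var_type <- "SNV"
    partner <- partner[, c("chrom", "pos", "ref", "alt", "var_type")]
  }
  new("PathogenicTarget", site = site, parent = parent,
      inheritance = inheritance, partnerSite = partner)
}

# is the partner allele the same variant as the primary one?
sameVariant <- function(target) {
  p <- target@partnerSite
  nrow(p) == 1L && p$chrom == target@site$chrom && p$pos == target@site$pos
}

# which parents carry which target site index in a map
carrierTable <- function(map) {
  tg <- targetSpec(map)
  if (is.null(tg)) return(data.frame(site = integer(0), parent = character(0)))
  s <- markerSites(map)
  other <- if (tg@parent == "maternal") "paternal" else "maternal"
  out <- data.frame(
    site = which(s$role == "target" & s$chrom == tg@site$chrom &
                 s$pos == tg@site$pos),
    parent = tg@parent, stringsAsFactors = FALSE)
  if (nrow(tg@partnerSite) == 1L) {
    p <- tg@partnerSite
    out <- rbind(out, data.frame(
      site = which(s$role == "target" & s$chrom == p$chrom & s$pos == p$pos),
      parent = other))
  }
  out
}

#' Build a marker map over a genomic region
#'
#' Draws `nMarkers` distinct marker positions uniformly over the region,
#' assigns each a minor-allele frequency from `mafRange`, and inserts the
#' pathogenic target site(s) at their specified positions. For the
#' informative-SNP window of +/-2 Mb around the target to be fully usable the
#' region should be at least 4 Mb.
#'
#' @param chrom Chromosome name.
#' @param start,end Region bounds, 1-based inclusive.
#' @param nMarkers Number of marker sites (>= 2).
#' @param mafRange Length-2 numeric: uniform MAF range for markers.
#' @param target Optional [PathogenicTarget-class]; its site(s) on this
#'   chromosome are inserted with role `target`.
#' @param seed Integer seed.
#' @return A [MarkerMap-class].
#' @examples
#' tg <- pathogenicTarget("chr11", 5248200, "A", "T", parent = "paternal")
#' buildMarkerMap("chr11", 3248200, 7248200, nMarkers = 50, target = tg, seed = 7)
#' @export
buildMarkerMap <- function(chrom, start, end, nMarkers,
                           mafRange = c(0.2, 0.5), target = NULL, seed = 1L) {
  assertCount(nMarkers, "nMarkers", min = 2L)
  if (end <= start) stopf("empty region %s:%d-%d", chrom, start, end)
  tsites <- NULL
  if (!is.null(target)) {
    validObject(target)
    cand <- rbind(target@site, target@partnerSite)
    cand <- unique(cand[cand$chrom == chrom, , drop = FALSE])
    if (nrow(cand) > 0L) {
      if (any(cand$pos < start | cand$pos > end))
        stopf("target site outside region %s:%d-%d", chrom, start, end)
      tsites <- cand
    }
  }
  nTarget <- if (is.null(tsites)) 0L else nrow(tsites)
  avail <- (end - start + 1) - nTarget
  if (avail < nMarkers)
    stopf("region %s:%d-%d cannot hold %d distinct marker positions",
          chrom, start, end, nMarkers)
  withSeed(seed, {
    pos <- numeric(0)
    excl <- if (nTarget) tsites$pos else numeric(0)
    while (length(pos) < nMarkers) {
      p <- unique(round(stats::runif(2L * nMarkers, start, end)))
      p <- setdiff(p, c(pos, excl))
      pos <- c(pos, p)
    }
    pos <- sort(pos[seq_len(nMarkers)])
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nMarkers, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
    maf <- stats::runif(nMarkers, mafRange[1], mafRange[2])
    sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                        var_type = "SNV", role = "marker", maf = maf,
                        stringsAsFactors = FALSE)
    if (nTarget) {
      tg <- data.frame(chrom = tsites$chrom, pos = tsites$pos,
                       ref = tsites$ref, alt = tsites$alt,
                       var_type = tsites$var_type, role = "target",
                       maf = NA_real_, stringsAsFactors = FALSE)
      sites <- rbind(sites, tg)
      sites <- sites[order(sites$pos), ]
    }
    rownames(sites) <- NULL
    new("MarkerMap",
        regions = data.frame(chrom = chrom, start = start, end = end,
                             stringsAsFactors = FALSE),
        sites = sites, target = target)
  })
}

#' Combine marker maps on disjoint chromosomes into one genome map
#'
#' @param ... [MarkerMap-class] objects on distinct chromosomes.
#' @return A single [MarkerMap-class]; at most one input may carry a target
#'   specification.
#' @export
combineMarkerMaps <- function(...) {
  maps <- list(...)
  if (length(maps) == 1L && is.list(maps[[1]]) && !is(maps[[1]], "MarkerMap"))
    maps <- maps[[1]]
  regions <- do.call(rbind, lapply(maps, mapRegions))
  if (anyDuplicated(regions$chrom))
    stopf("combined maps must live on distinct chromosomes")
  targets <- Filter(Negate(is.null), lapply(maps, targetSpec))
  if (length(targets) > 1L) stopf("at most one map may carry a target spec")
  sites <- do.call(rbind, lapply(maps, markerSites))
  rownames(sites) <- NULL
  new("MarkerMap", regions = regions, sites = sites,
      target = if (length(targets)) targets[[1]] else NULL)
}

#' Restrict a marker map to one chromosome
#' @param map A [MarkerMap-class].
#' @param chrom Chromosome to keep.
#' @return A [MarkerMap-class]; the target spec is kept only if it lies on
#'   `chrom`. The attribute `siteOffset` gives the index of the first kept
#'   site in the parent map.
#' @export
subsetMapByChrom <- function(map, chrom) {
  s <- markerSites(map)
  keep <- s$chrom == chrom
  if (!any(keep)) stopf("no sites on %s", chrom)
  tg <- targetSpec(map)
  if (!is.null(tg) && tg@site$chrom != chrom &&
      !(nrow(tg@partnerSite) && tg@partnerSite$chrom == chrom))
    tg <- NULL
  out <- new("MarkerMap",
             regions = mapRegions(map)[mapRegions(map)$chrom == chrom, , drop = FALSE],
             sites = s[keep, ], target = tg)
  attr(out, "siteOffset") <- which(keep)[1] - 1L
  out
}

#' Simulate phased parental truth over a marker map
#'
#' Each parent receives two haplotype allele vectors. Marker alleles are
#' drawn per haplotype from the site's MAF; any marker heterozygous in
#' neither parent is re-drawn heterozygous in a randomly chosen parent, so
#' every marker carries phase information for at least one parent. Each
#' designated carrier parent receives the target alt allele on exactly one
#' uniformly chosen haplotype; non-carriers are homozygous reference there.
#'
#' @param map A [MarkerMap-class].
#' @param seed Integer seed.
#' @param hetIn Which parent(s) every marker is forced heterozygous in:
#'   `"either"` (default; a random parent is made heterozygous wherever
#'   neither is), `"maternal"` or `"paternal"` (the phasing workup's marker
#'   set is by construction the focal carrier's heterozygous SNPs), or
#'   `"both"`.
#' @return A [ParentalTruth-class].
#' @export
makeParentalTruth <- function(map, seed = 1L,
                              hetIn = c("either", "maternal", "paternal",
                                        "both")) {
  validObject(map)
  hetIn <- match.arg(hetIn)
  s <- markerSites(map)
  n <- nrow(s)
  withSeed(seed, {
    haps <- list()
    for (parent in c("maternal", "paternal")) {
      h <- matrix(0L, nrow = 2L, ncol = n)
      mk <- s$role == "marker"
      h[1, mk] <- stats::rbinom(sum(mk), 1L, s$maf[mk])
      h[2, mk] <- stats::rbinom(sum(mk), 1L, s$maf[mk])
      haps[[parent]] <- h
    }
    # enforce the configured heterozygosity pattern at every marker
    mk <- which(s$role == "marker")
    forceHet <- function(parent, at) {
      hapWithAlt <- sample(1:2, length(at), replace = TRUE)
      for (k in seq_along(at)) {
        haps[[parent]][, at[k]] <<- 0L
        haps[[parent]][hapWithAlt[k], at[k]] <<- 1L
      }
    }
    hetOf <- function(parent)
      haps[[parent]][1, mk] != haps[[parent]][2, mk]
    if (hetIn %in% c("maternal", "both"))
      forceHet("maternal", mk[!hetOf("maternal")])
    if (hetIn %in% c("paternal", "both"))
      forceHet("paternal", mk[!hetOf("paternal")])
    if (hetIn == "either") {
      fix <- mk[!hetOf("maternal") & !hetOf("paternal")]
      if (length(fix)) {
        who <- sample(c("maternal", "paternal"), length(fix), replace = TRUE)
        for (p in c("maternal", "paternal"))
          forceHet(p, fix[who == p])
      }
    }
    # place target alleles
    ct <- carrierTable(map)
    for (parent in c("maternal", "paternal")) {
      idx <- ct$site[ct$parent == parent]
      for (i in targetIndices(map)) {
        haps[[parent]][, i] <- 0L
        if (i %in% idx) haps[[parent]][sample(1:2, 1L), i] <- 1L
      }
    }
    geno <- lapply(haps, function(h)
      paste(pmin(h[1, ], h[2, ]), pmax(h[1, ], h[2, ]), sep = "/"))
    new("ParentalTruth", map = map, haplotypes = haps, genotypes = geno)
  })
}

# index range of map sites covered by a 0-based half-open interval
sitesInInterval <- function(pos, start, end) {
  # site at 1-based pos is inside [start, end) iff start < pos <= end
  lo <- findInterval(start + 0.5, pos) + 1L
  hi <- findInterval(end + 0.5, pos)
  if (hi < lo) integer(0) else lo:hi
}

#' Simulate barcoded linked-read fragments from one parent
#'
#' Each molecule is drawn from one of the parent's two haplotypes (chosen
#' uniformly), placed uniformly over the map regions, and observes the
#' allele of its source haplotype at every marker site inside its interval;
#' each observed allele is flipped independently with probability
#' `perSiteError`. One barcode corresponds to one molecule. Molecule
#' lengths follow a gamma distribution with the given mean and standard
#' deviation, truncated at 1 kb; the default sd equals the mean, i.e. the
#' exponential length law of randomly sheared high-molecular-weight DNA,
#' whose heavy tail supplies the long molecules that bridge sparse
#' heterozygous sites.
#'
#' @param truth A [ParentalTruth-class].
#' @param parent `"maternal"` or `"paternal"`.
#' @param nFragments Number of molecules.
#' @param fragLenMean,fragLenSd Fragment length mean and sd in bp (default
#'   mean 40 kb, within the 36.9-48.8 kb range typical of linked-read
#'   libraries; default sd = mean).
#' @param perSiteError Per-observation allele error probability (< 0.5).
#' @param seed Integer seed.
#' @param chrom Optional chromosome filter: fragments are only generated
#'   over this region.
#' @param qualRange Phred-like quality range for observations.
#' @return A [FragmentSet-class].
#' @export
simulateFragments <- function(truth, parent = "maternal", nFragments,
                              fragLenMean = 40000, fragLenSd = fragLenMean,
                              perSiteError = 0.02, seed = 1L, chrom = NULL,
                              qualRange = c(55, 60)) {
  assertCount(nFragments, "nFragments")
  if (fragLenMean <= 0) stopf("'fragLenMean' must be positive")
  assertProb(perSiteError, "perSiteError", maxExclusive = 0.5)
  map <- truthMap(truth)
  reg <- mapRegions(map)
  if (!is.null(chrom)) reg <- reg[reg$chrom %in% chrom, , drop = FALSE]
  if (nrow(reg) == 0L) stopf("no regions to simulate fragments over")
  s <- markerSites(map)
  hap <- truthHaplotypes(truth)[[parent]]
  withSeed(seed, {
    shape <- (fragLenMean / fragLenSd)^2
    lens <- pmax(1000, round(stats::rgamma(nFragments, shape = shape,
                                           scale = fragLenSd^2 / fragLenMean)))
    w <- reg$end - reg$start + 1
    ri <- sample.int(nrow(reg), nFragments, replace = TRUE, prob = w)
    # 0-based start; fragment may start before the region so that region
    # edges are covered without biasing the length distribution
    start <- floor(stats::runif(nFragments, reg$start[ri] - 1 - lens,
                                reg$end[ri]))
    end <- start + lens
    hapIdx <- sample(1:2, nFragments, replace = TRUE)
    obsList <- vector("list", nFragments)
    for (rix in seq_len(nrow(reg))) {
      ch <- reg$chrom[rix]
      sIdx <- which(s$chrom == ch)
      if (!length(sIdx)) next
      pos <- s$pos[sIdx]
      for (f in which(ri == rix)) {
        cover <- sitesInInterval(pos, start[f], end[f])
        if (!length(cover)) next
        sites <- sIdx[cover]
        allele <- hap[hapIdx[f], sites]
        flip <- stats::runif(length(sites)) < perSiteError
        allele[flip] <- 1L - allele[flip]
        obsList[[f]] <- data.frame(
          fragment = f, site = sites, allele = as.integer(allele),
          qual = round(stats::runif(length(sites), qualRange[1], qualRange[2])))
      }
    }
    obs <- do.call(rbind, obsList)
    if (is.null(obs))
      obs <- data.frame(fragment = integer(0), site = integer(0),
                        allele = integer(0), qual = numeric(0))
    frags <- data.frame(
      barcode = sprintf("BX%06d", seq_len(nFragments)),
      chrom = reg$chrom[ri], start = start, end = end, hap = hapIdx,
      stringsAsFactors = FALSE)
    new("FragmentSet", parent = parent, fragments = frags,
        observations = obs, nSites = nrow(s))
  })
}

#' Simulate the meiotic truth of one embryo
#'
#' Chooses (or accepts) the transmitted haplotype of each parent per
#' chromosome, switches it at the given crossover positions, and attaches
#' the embryo's ploidy state, mosaic fraction and forced-homozygous (ROH)
#' regions.
#'
#' @param truth A [ParentalTruth-class].
#' @param crossovers data.frame with columns `parent`, `chrom`, `pos`
#'   (1-based, strictly inside the region), or a list
#'   `list(maternal = positions, paternal = positions)` for single-region
#'   maps.
#' @param ploidy `"diploid"`, `"haploid"`, `"triploid"`, `"trisomy"`,
#'   `"monosomy"` or `"segmental"`.
#' @param chrom Chromosome of a trisomy/monosomy/segmental event.
#' @param segStart,segEnd Segment bounds (0-based half-open) for
#'   `ploidy = "segmental"`.
#' @param segDirection `"gain"` or `"loss"` for segmental events.
#' @param mosaicFraction Abnormal-cell fraction in (0, 1]; must be 1 for
#'   non-mosaic states and is only meaningful for copy-number abnormalities.
#' @param rohRegions Optional data.frame `chrom`, `start`, `end` (0-based
#'   half-open) forced homozygous.
#' @param transmit Optional named list fixing the transmitted haplotype per
#'   parent: an integer 1/2 (applies to all chromosomes) or `"risk"` /
#'   `"nonrisk"` (resolved on the target's chromosome; other chromosomes
#'   stay random).
#' @param seed Integer seed.
#' @return An [EmbryoTruth-class].
#' @export
simulateEmbryo <- function(truth, crossovers = NULL, ploidy = "diploid",
                           chrom = NA_character_, segStart = NA_real_,
                           segEnd = NA_real_, segDirection = "gain",
                           mosaicFraction = 1, rohRegions = NULL,
                           transmit = NULL, seed = 1L) {
  map <- truthMap(truth)
  s <- markerSites(map)
  reg <- mapRegions(map)
  if (is.null(crossovers))
    crossovers <- data.frame(parent = character(0), chrom = character(0),
                             pos = numeric(0))
  if (is.list(crossovers) && !is.data.frame(crossovers)) {
    if (nrow(reg) != 1L)
      stopf("list-form crossovers need a single-region map; use a data.frame")
    crossovers <- do.call(rbind, lapply(names(crossovers), function(p)
      if (length(crossovers[[p]]))
        data.frame(parent = p, chrom = reg$chrom, pos = crossovers[[p]])
      else NULL))
    if (is.null(crossovers))
      crossovers <- data.frame(parent = character(0), chrom = character(0),
                               pos = numeric(0))
  }
  for (k in seq_len(nrow(crossovers))) {
    r <- reg[reg$chrom == crossovers$chrom[k], ]
    if (nrow(r) != 1L || crossovers$pos[k] <= r$start || crossovers$pos[k] >= r$end)
      stopf("crossover at %s:%g is outside the simulated region",
            crossovers$chrom[k], crossovers$pos[k])
  }
  if (is.null(rohRegions))
    rohRegions <- data.frame(chrom = character(0), start = numeric(0),
                             end = numeric(0))
  seg <- if (ploidy == "segmental") {
    if (is.na(segStart) || is.na(segEnd) || is.na(chrom))
      stopf("segmental ploidy needs 'chrom', 'segStart' and 'segEnd'")
    data.frame(chrom = chrom, start = segStart, end = segEnd,
               direction = segDirection, stringsAsFactors = FALSE)
  } else data.frame(chrom = character(0), start = numeric(0),
                    end = numeric(0), direction = character(0))
  withSeed(seed, {
    targetChrom <- if (!is.null(targetSpec(map))) targetSpec(map)@site$chrom
                   else NA_character_
    transmitted <- list()
    for (parent in c("maternal", "paternal")) {
      lab <- integer(nrow(s))
      for (ch in reg$chrom) {
        idx <- which(s$chrom == ch)
        want <- if (!is.null(transmit)) transmit[[parent]] else NULL
        startHap <-
          if (is.numeric(want)) as.integer(want)
          else if (is.character(want) && identical(ch, targetChrom)) {
            ct <- carrierTable(map)
            tIdx <- ct$site[ct$parent == parent][1]
            if (is.na(tIdx))
              sample(1:2, 1L)
            else {
              riskHap <- which(truthHaplotypes(truth)[[parent]][, tIdx] == 1L)
              if (want == "risk") riskHap else 3L - riskHap
            }
          } else sample(1:2, 1L)
        co <- sort(crossovers$pos[crossovers$parent == parent &
                                  crossovers$chrom == ch])
        switches <- if (length(co)) findInterval(s$pos[idx], co) else 0L
        lab[idx] <- 1L + (startHap - 1L + switches) %% 2L
      }
      transmitted[[parent]] <- lab
    }
    extraParent <- if (ploidy %in% c("triploid", "trisomy")) "maternal"
                   else NA_character_
    new("EmbryoTruth", map = map, transmitted = transmitted,
        crossovers = crossovers, ploidy = ploidy,
        ploidyChrom = as.character(chrom), segment = seg,
        mosaicFraction = mosaicFraction, rohRegions = rohRegions,
        extra = list(parent = extraParent))
  })
}

# per-site allele template (list of integer allele vectors) for one embryo
embryoTemplates <- function(embryo, truth) {
  map <- truthMap(truth)
  s <- markerSites(map)
  haps <- truthHaplotypes(truth)
  tm <- embryo@transmitted
  n <- nrow(s)
  matAl <- haps$maternal[cbind(tm$maternal, seq_len(n))]
  patAl <- haps$paternal[cbind(tm$paternal, seq_len(n))]
  # additional copy for triploid/trisomic genomes: the carrier parent's
  # non-transmitted haplotype (digynic model)
  extraAl <- haps$maternal[cbind(3L - tm$maternal, seq_len(n))]
  inChrom <- s$chrom == embryo@ploidyChrom
  tmpl <- switch(embryo@ploidy,
    diploid = mapply(c, matAl, patAl, SIMPLIFY = FALSE),
    haploid = as.list(matAl),
    triploid = mapply(c, matAl, patAl, extraAl, SIMPLIFY = FALSE),
    trisomy = {
      t0 <- mapply(c, matAl, patAl, SIMPLIFY = FALSE)
      if (embryo@mosaicFraction == 1)
        t0[inChrom] <- mapply(c, matAl[inChrom], patAl[inChrom],
                              extraAl[inChrom], SIMPLIFY = FALSE)
      t0
    },
    monosomy = {
      t0 <- mapply(c, matAl, patAl, SIMPLIFY = FALSE)
      if (embryo@mosaicFraction == 1) t0[inChrom] <- as.list(matAl[inChrom])
      t0
    },
    segmental = {
      t0 <- mapply(c, matAl, patAl, SIMPLIFY = FALSE)
      if (embryo@mosaicFraction == 1) {
        sg <- embryo@segment
        inSeg <- s$chrom == sg$chrom & s$pos - 1 >= sg$start & s$pos - 1 < sg$end
        if (sg$direction == "gain")
          t0[inSeg] <- mapply(c, matAl[inSeg], patAl[inSeg], matAl[inSeg],
                              SIMPLIFY = FALSE)
        else t0[inSeg] <- as.list(matAl[inSeg])
      }
      t0
    },
    stopf("unknown ploidy '%s'", embryo@ploidy))
  # forced-homozygous (ROH) intervals: isodisomy of the transmitted maternal
  # allele
  roh <- embryo@rohRegions
  for (k in seq_len(nrow(roh))) {
    inRoh <- s$chrom == roh$chrom[k] & s$pos - 1 >= roh$start[k] &
             s$pos - 1 < roh$end[k]
    tmpl[inRoh] <- lapply(matAl[inRoh], function(a) c(a, a))
  }
  tmpl
}

#' Simulate post-MDA embryo genotype calls
#'
#' Computes each site's true allele template from the transmitted
#' haplotypes (including abnormal-ploidy templates), applies symmetric
#' single-allele dropout to heterozygous diploid sites with probability
#' `adoRate`, samples Poisson read depths and binomial alternate-allele
#' counts with a per-read error, and calls genotypes with a naive B-allele
#' frequency threshold caller (het band 0.2-0.8; `"./."` at zero depth).
#'
#' @param embryo An [EmbryoTruth-class].
#' @param truth The [ParentalTruth-class] it was drawn from.
#' @param meanDepth Mean read depth per site.
#' @param adoRate Allele-dropout probability per heterozygous site.
#' @param perReadError Per-read allele error probability.
#' @param callError Per-site probability of a post-hoc genotype miscall
#'   (hom and het calls are exchanged); models residual genotyping error
#'   beyond read sampling. Default 0.
#' @param embryoId Identifier stored with the table.
#' @param seed Integer seed.
#' @return An [EmbryoGenotypes-class].
#' @export
simulateEmbryoGenotypes <- function(embryo, truth, meanDepth = 30,
                                    adoRate = 0.10, perReadError = 0.01,
                                    callError = 0, embryoId = "E1",
                                    seed = 1L) {
  assertProb(adoRate, "adoRate")
  assertProb(perReadError, "perReadError", maxExclusive = 0.5)
  map <- truthMap(truth)
  s <- markerSites(map)
  tmpl <- embryoTemplates(embryo, truth)
  n <- nrow(s)
  withSeed(seed, {
    nAl <- lengths(tmpl)
    altN <- vapply(tmpl, sum, numeric(1))
    het2 <- nAl == 2L & altN == 1L
    drop <- het2 & stats::runif(n) < adoRate
    # dropout removes one allele of the heterozygote uniformly
    keepAlt <- stats::runif(n) < 0.5
    pTrue <- altN / nAl
    pTrue[drop] <- ifelse(keepAlt[drop], 1, 0)
    p <- pTrue * (1 - perReadError) + (1 - pTrue) * perReadError
    dp <- stats::rpois(n, meanDepth)
    altDp <- stats::rbinom(n, dp, p)
    baf <- ifelse(dp > 0, altDp / dp, NA_real_)
    gt <- rep("./.", n)
    ok <- dp > 0
    gt[ok & baf < 0.2] <- "0/0"
    gt[ok & baf > 0.8] <- "1/1"
    gt[ok & baf >= 0.2 & baf <= 0.8] <- "0/1"
    if (callError > 0) {
      flip <- ok & stats::runif(n) < callError
      gt[flip] <- ifelse(gt[flip] == "0/1",
                         ifelse(baf[flip] < 0.5, "0/0", "1/1"),
                         "0/1")
    }
    calls <- data.frame(site = seq_len(n), chrom = s$chrom, pos = s$pos,
                        gt = gt, dp = dp, altDp = altDp, baf = baf,
                        stringsAsFactors = FALSE)
    new("EmbryoGenotypes", embryoId = embryoId, map = map, calls = calls)
  })
}

#' Fixed-width window grid over the map regions
#'
#' @param map A [MarkerMap-class].
#' @param windowWidth Window width in bp (default 1 Mb).
#' @return data.frame `chrom`, `start`, `end` (0-based half-open).
#' @export
makeWindows <- function(map, windowWidth = 1e6) {
  if (windowWidth <= 0) stopf("window width must be positive")
  reg <- mapRegions(map)
  out <- lapply(seq_len(nrow(reg)), function(i) {
    lo <- reg$start[i] - 1
    starts <- seq(lo, reg$end[i] - 1, by = windowWidth)
    data.frame(chrom = reg$chrom[i], start = starts,
               end = pmin(starts + windowWidth, reg$end[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# expected local copy number per window for an embryo truth
windowCopyNumber <- function(embryo, windows) {
  cn <- rep(2, nrow(windows))
  mid <- (windows$start + windows$end) / 2
  f <- embryo@mosaicFraction
  apply_cn <- function(sel, cnAbn) cn[sel] <<- 2 + f * (cnAbn - 2)
  switch(embryo@ploidy,
    diploid = NULL,
    haploid = apply_cn(rep(TRUE, nrow(windows)), 1),
    triploid = apply_cn(rep(TRUE, nrow(windows)), 3),
    trisomy = apply_cn(windows$chrom == embryo@ploidyChrom, 3),
    monosomy = apply_cn(windows$chrom == embryo@ploidyChrom, 1),
    segmental = {
      sg <- embryo@segment
      sel <- windows$chrom == sg$chrom & mid >= sg$start & mid < sg$end
      apply_cn(sel, if (sg$direction == "gain") 3 else 1)
    })
  cn
}

#' Simulate per-window read counts and a diploid reference panel
#'
#' Test counts are negative binomial with mean
#' `meanCount * CN / 2` where the local copy number CN is
#' `2 + f * (cnAbnormal - 2)` for mosaic fraction `f`; the reference panel
#' consists of `nReference` diploid samples generated identically at CN 2.
#'
#' @param embryo An [EmbryoTruth-class].
#' @param windowWidth Window width in bp.
#' @param meanCount Mean reads per diploid window.
#' @param dispersion Negative-binomial overdispersion (`size = 1/dispersion`);
#'   0 gives Poisson counts.
#' @param nReference Number of diploid reference samples.
#' @param seed Integer seed.
#' @return A [WindowCountTrack-class].
#' @export
simulateWindowCounts <- function(embryo, windowWidth = 1e6, meanCount = 100,
                                 dispersion = 0.05, nReference = 20,
                                 seed = 1L) {
  if (meanCount <= 0) stopf("'meanCount' must be positive")
  assertCount(nReference, "nReference")
  windows <- makeWindows(embryo@map, windowWidth)
  cn <- windowCopyNumber(embryo, windows)
  nw <- nrow(windows)
  rcount <- function(n, mu) {
    if (dispersion > 0) stats::rnbinom(n, mu = mu, size = 1 / dispersion)
    else stats::rpois(n, mu)
  }
  withSeed(seed, {
    test <- rcount(nw, meanCount * cn / 2)
    ref <- matrix(rcount(nw * nReference, meanCount), nrow = nw)
    colnames(ref) <- sprintf("REF%02d", seq_len(nReference))
    new("WindowCountTrack", windows = windows, test = as.numeric(test),
        reference = ref, log2rr = rep(NA_real_, nw),
        masked = rep(FALSE, nw))
  })
}
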