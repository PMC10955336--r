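# Parental haplotype construction from barcoded fragment evidence.
#
# The phaser is a greedy minimum-error-correction (MEC) assembler: adjacent
# and co-observed heterozygous sites are connected by edges weighted by
# (consistent - inconsistent) co-observations, components are 2-colored by a
# maximum-agreement spanning order (edges processed by descending |weight|),
# and the coloring is refined by single-site flips that strictly decrease
# the MEC objective. Blocks are then "signed" risk / non-risk by the allele
# their fragments carry at the pathogenic target site.

#' Filter fragments for phasing
#'
#' Masks observations below `minQuality`, optionally restricts observations
#' to a set of heterozygous sites, and drops fragments left with fewer than
#' `minSites` observations (a fragment covering fewer than two heterozygous
#' sites carries no phase information).
#'
#' @param fragments A [FragmentSet-class].
#' @param hetSites Optional integer vector of heterozygous site indices to
#'   keep observations at.
#' @param minSites Minimum observations per retained fragment (default 2).
#' @param minQuality Minimum observation quality (default 0 = keep all).
#' @return A filtered [FragmentSet-class] with fragments renumbered.
#' @export
filterFragments <- function(fragments, hetSites = NULL, minSites = 2L,
                            minQuality = 0) {
  ob <- fragmentObservations(fragments)
  keep <- ob$qual >= minQuality
  if (!is.null(hetSites)) keep <- keep & ob$site %in% hetSites
  ob <- ob[keep, , drop = FALSE]
  cnt <- table(ob$fragment)
  goodFrag <- as.integer(names(cnt)[cnt >= minSites])
  ob <- ob[ob$fragment %in% goodFrag, , drop = FALSE]
  goodFrag <- sort(goodFrag)
  remap <- integer(nrow(fragmentTable(fragments)))
  remap[goodFrag] <- seq_along(goodFrag)
  ob$fragment <- remap[ob$fragment]
  ob <- ob[order(ob$fragment, ob$site), , drop = FALSE]
  rownames(ob) <- NULL
  new("FragmentSet", parent = fragments@parent,
      fragments = fragmentTable(fragments)[goodFrag, , drop = FALSE],
      observations = ob, nSites = fragments@nSites)
}

# iterative union-find with parity (relative phase to the component root)
ufFind <- function(uf, i) {
  path <- integer(0)
  par <- 0L
  while (uf$parent[i] != i) {
    path <- c(path, i)
    par <- bitwXor(par, uf$par[i])
    i <- uf$parent[i]
  }
  # path compression with accumulated parity
  p <- par
  for (j in path) {
    pj <- uf$par[j]
    uf$parent[j] <- i
    uf$par[j] <- p
    p <- bitwXor(p, pj)
  }
  list(uf = uf, root = i, par = par)
}

#' Phase heterozygous sites from fragment evidence
#'
#' @param fragments A filtered [FragmentSet-class].
#' @param hetSites Integer vector of heterozygous site indices for the
#'   parent being phased.
#' @param refine Apply single-site flip refinement of the MEC objective
#'   (default TRUE).
#' @return A [PhasedHaplotypes-class]; one block per connected component of
#'   the co-observation graph (no heterozygous sites gives an empty result).
#' @export
phaseSites <- function(fragments, hetSites, refine = TRUE) {
  empty <- new("PhasedHaplotypes",
               sites = data.frame(site = integer(0), block = integer(0),
                                  hapA = integer(0), conf = numeric(0)),
               nFragments = 0L)
  if (length(hetSites) == 0L) return(empty)
  ob <- fragmentObservations(fragments)
  ob <- ob[ob$site %in% hetSites, , drop = FALSE]
  if (nrow(ob) == 0L) return(empty)
  usedSites <- sort(unique(ob$site))
  rank <- match(ob$site, usedSites)
  n <- length(usedSites)

  # co-observation edges within fragments
  sp <- split(seq_len(nrow(ob)), ob$fragment)
  edges <- vector("list", length(sp))
  for (k in seq_along(sp)) {
    rows <- sp[[k]]
    m <- length(rows)
    if (m < 2L) next
    pr <- utils::combn(rows, 2L)
    edges[[k]] <- data.frame(
      i = rank[pr[1, ]], j = rank[pr[2, ]],
      xor = bitwXor(ob$allele[pr[1, ]], ob$allele[pr[2, ]]))
  }
  edges <- do.call(rbind, edges)
  h <- integer(n)
  uf <- list(parent = seq_len(n), par = integer(n))
  if (!is.null(edges)) {
    key <- edges$i * (n + 1L) + edges$j
    nSame <- tapply(edges$xor == 0L, key, sum)
    nTot <- tapply(edges$xor, key, length)
    w <- 2L * as.integer(nSame) - as.integer(nTot)
    k2 <- as.numeric(names(nSame))
    ei <- as.integer(k2 %/% (n + 1L))
    ej <- as.integer(k2 %% (n + 1L))
    ordE <- order(-abs(w), ei, ej)
    for (e in ordE) {
      if (w[e] == 0L) next
      r <- if (w[e] > 0L) 0L else 1L   # desired parity between endpoints
      fi <- ufFind(uf, ei[e]); uf <- fi$uf
      fj <- ufFind(uf, ej[e]); uf <- fj$uf
      if (fi$root == fj$root) next      # keep higher-weight evidence
      uf$parent[fj$root] <- fi$root
      uf$par[fj$root] <- bitwXor(bitwXor(fi$par, fj$par), r)
    }
  }
  root <- integer(n)
  for (i in seq_len(n)) {
    f <- ufFind(uf, i); uf <- f$uf
    root[i] <- f$root
    h[i] <- f$par
  }
  block <- match(root, unique(root[order(usedSites)]))
  # normalize orientation: first site of each block carries hap-A allele 0
  for (b in unique(block)) {
    sel <- block == b
    if (h[sel][1] == 1L) h[sel] <- 1L - h[sel]
  }

  # MEC refinement over fragment-block pieces: greedy single-site flips plus
  # block suffix flips (a mis-oriented tail after a weak junction changes
  # every site past the junction; single-site moves cannot cross that
  # barrier, a suffix flip can)
  piece <- interaction(ob$fragment, block[rank], drop = TRUE)
  pieceId <- as.integer(piece)
  len <- tabulate(pieceId)
  mism <- ob$allele != h[rank]
  mA <- as.numeric(tapply(mism, pieceId, sum))
  obsBySite <- split(seq_len(nrow(ob)), rank)
  flipSite <- function(i) {
    rows <- obsBySite[[as.character(i)]]
    if (!is.null(rows)) {
      pid <- pieceId[rows]
      mA[pid] <<- mA[pid] + ifelse(ob$allele[rows] == h[i], 1, -1)
    }
    h[i] <<- 1L - h[i]
  }
  deltaSite <- function(i) {
    rows <- obsBySite[[as.character(i)]]
    if (is.null(rows)) return(0)
    pid <- pieceId[rows]
    mAnew <- mA[pid] + ifelse(ob$allele[rows] == h[i], 1, -1)
    sum(pmin(mAnew, len[pid] - mAnew) - pmin(mA[pid], len[pid] - mA[pid]))
  }
  if (refine && !is.null(edges)) {
    blocksList <- split(seq_len(n), block)
    for (outer in seq_len(5L)) {
      changed <- FALSE
      # single-site descent
      for (pass in seq_len(20L)) {
        inner <- FALSE
        for (i in seq_len(n)) if (deltaSite(i) < 0) {
          flipSite(i); inner <- TRUE; changed <- TRUE
        }
        if (!inner) break
      }
      # suffix-flip descent per block
      for (bs in blocksList) {
        m <- length(bs)
        if (m < 3L) next
        h0 <- h; mA0 <- mA
        total0 <- sum(pmin(mA, len - mA))
        best <- 0; bestK <- NA_integer_
        run <- total0
        for (k in m:2) {
          rows <- obsBySite[[as.character(bs[k])]]
          if (!is.null(rows)) {
            pid <- pieceId[rows]
            old <- pmin(mA[pid], len[pid] - mA[pid])
            flipSite(bs[k])
            run <- run + sum(pmin(mA[pid], len[pid] - mA[pid])) - sum(old)
          } else flipSite(bs[k])
          if (run - total0 < best) { best <- run - total0; bestK <- k }
        }
        h <- h0; mA <- mA0
        if (!is.na(bestK)) {
          for (k in bestK:m) flipSite(bs[k])
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    # re-normalize orientation after refinement
    for (b in unique(block)) {
      sel <- block == b
      if (h[sel][1] == 1L) {
        h[sel] <- 1L - h[sel]
        inB <- block[rank] == b
        mA[unique(pieceId[inB])] <-
          len[unique(pieceId[inB])] - mA[unique(pieceId[inB])]
      }
    }
  }

  # per-site confidence: fraction of covering fragments consistent with the
  # phase once each fragment piece is assigned to its best haplotype
  assignA <- mA <= len - mA
  consistent <- ifelse(assignA[pieceId], ob$allele == h[rank],
                       ob$allele == 1L - h[rank])
  conf <- as.numeric(tapply(consistent, rank, mean))
  sites <- data.frame(site = usedSites, block = block, hapA = as.integer(h),
                      conf = conf)
  sites <- sites[order(sites$site), ]
  rownames(sites) <- NULL
  new("PhasedHaplotypes", sites = sites,
      nFragments = length(unique(ob$fragment)))
}

#' Minimum-error-correction score of a haplotype pair
#'
#' Sums over fragments the smaller of the mismatch counts against haplotype
#' A and its complement B; this is the number of allele flips needed to make
#' every fragment consistent with the pair.
#'
#' @param fragments A [FragmentSet-class].
#' @param haplotype Either an integer 0/1 vector indexed by site (NA =
#'   unphased) or a [PhasedHaplotypes-class]/its site data.frame.
#' @return Integer MEC score (0 for an empty fragment set).
#' @export
mecScore <- function(fragments, haplotype) {
  if (is(haplotype, "PhasedHaplotypes")) haplotype <- phasedSites(haplotype)
  if (is.data.frame(haplotype)) {
    h <- rep(NA_integer_, fragments@nSites)
    h[haplotype$site] <- haplotype$hapA
    haplotype <- h
  }
  ob <- fragmentObservations(fragments)
  if (nrow(ob) == 0L) return(0L)
  hv <- haplotype[ob$site]
  if (anyNA(hv))
    stopf("fragment observation at unphased site %s",
          paste(unique(ob$site[is.na(hv)]), collapse = ", "))
  mism <- as.integer(ob$allele != hv)
  m <- tapply(mism, ob$fragment, sum)
  k <- tapply(mism, ob$fragment, length)
  as.integer(sum(pmin(m, k - m)))
}

#' Sign phased haplotypes as risk / non-risk at the pathogenic target
#'
#' Fragments spanning the target vote with the allele they carry there; the
#' haplotype whose fragments carry the alt allele is labelled risk. Signing
#' is an explicit no-call when fewer than `minSpanReads` fragments span the
#' target or when fewer than `minConsistency` of the spanning fragments
#' agree with the majority phase.
#'
#' @param phased A [PhasedHaplotypes-class] for the carrier parent.
#' @param fragments The [FragmentSet-class] used for phasing.
#' @param map The [MarkerMap-class].
#' @param carrierGenotype The carrier's genotype string at the target; must
#'   be heterozygous.
#' @param parent Parent label (`"maternal"`/`"paternal"`).
#' @param targetSite Site index of the target; defaults to this parent's
#'   carried target from the map's target spec.
#' @param minSpanReads Minimum target-spanning fragments (default 5).
#' @param minConsistency Minimum majority consistency (default 0.8).
#' @return A [SignedHaplotypePair-class] with `call` `"signed"` or
#'   `"nocall"`.
#' @export
signHaplotypes <- function(phased, fragments, map, carrierGenotype,
                           parent = "maternal", targetSite = NULL,
                           minSpanReads = 5L, minConsistency = 0.8) {
  if (!isHetGt(carrierGenotype))
    stopf("carrier is not heterozygous at the target; cannot sign haplotypes")
  if (is.null(targetSite)) {
    ct <- carrierTable(map)
    targetSite <- ct$site[ct$parent == parent][1]
    if (is.na(targetSite) || length(targetSite) == 0L)
      stopf("no target site designated for the %s parent", parent)
  }
  targetSite <- as.integer(targetSite)
  targetPos <- markerSites(map)$pos[targetSite]
  phs <- phasedSites(phased)
  if (!targetSite %in% phs$site)
    stop(structure(class = c("phaselink_unsigned", "error", "condition"),
                   list(message = sprintf(
                     "target site %d is not in any phased block; haplotypes unsigned",
                     targetSite), call = NULL)))
  tBlock <- phs$block[phs$site == targetSite]
  hT <- phs$hapA[phs$site == targetSite]
  blockSites <- phs$site[phs$block == tBlock]
  hBlock <- phs$hapA[phs$block == tBlock]
  names(hBlock) <- blockSites

  ob <- fragmentObservations(fragments)
  span <- unique(ob$fragment[ob$site == targetSite])
  nSpan <- length(span)
  mkPair <- function(call, riskHap = NA_character_, consistency = NA_real_) {
    pos <- markerSites(map)$pos[blockSites]
    up <- pos[pos < targetPos]; down <- pos[pos > targetPos]
    new("SignedHaplotypePair", parent = parent, phased = phased,
        targetSite = targetSite, targetPos = targetPos, call = call,
        riskHap = riskHap, consistency = consistency,
        spanningReads = as.integer(nSpan),
        spanUp = if (length(up)) targetPos - min(up) else 0,
        spanDown = if (length(down)) max(down) - targetPos else 0,
        informative = data.frame(site = integer(0), pos = numeric(0),
                                 side = character(0), distance = numeric(0),
                                 riskAllele = integer(0),
                                 otherGt = character(0)))
  }
  if (nSpan < minSpanReads) return(mkPair("nocall"))

  # assign each spanning fragment to hap A or B by its non-target block
  # observations, then check its target allele against the assigned phase
  inBlock <- ob$fragment %in% span & ob$site %in% blockSites
  obB <- ob[inBlock, , drop = FALSE]
  other <- obB[obB$site != targetSite, , drop = FALSE]
  if (nrow(other)) {
    mismA <- other$allele != hBlock[as.character(other$site)]
    mA <- tapply(mismA, other$fragment, sum)
    kk <- tapply(mismA, other$fragment, length)
    assign <- ifelse(mA < kk - mA, "A", ifelse(mA > kk - mA, "B", NA))
  } else assign <- character(0)
  tObs <- obB[obB$site == targetSite, , drop = FALSE]
  asg <- assign[as.character(tObs$fragment)]
  ok <- !is.na(asg)
  if (!any(ok)) return(mkPair("nocall"))
  consistent <- ifelse(asg[ok] == "A", tObs$allele[ok] == hT,
                       tObs$allele[ok] == 1L - hT)
  consistency <- mean(consistent)
  if (consistency < minConsistency) return(mkPair("nocall", consistency = consistency))
  mkPair("signed", riskHap = if (hT == 1L) "A" else "B",
         consistency = consistency)
}

#' Select informative SNPs around the target
#'
#' A marker is informative for the signed (carrier) parent when that parent
#' is heterozygous and phased in the target's block, the marker lies within
#' `windowBp` of the target on either side, and the other parent is
#' homozygous there - so the embryo genotype deterministically reveals which
#' of the carrier's haplotypes was transmitted. Sites where both parents are
#' heterozygous cannot discriminate parent of origin and are excluded.
#'
#' @param signed A signed [SignedHaplotypePair-class].
#' @param otherGenotypes Character vector of the other parent's genotype
#'   strings, indexed by site.
#' @param map The [MarkerMap-class].
#' @param windowBp Window half-width in bp on each side (default 2,000,000).
#' @return The [SignedHaplotypePair-class] with its `informative` table
#'   filled; a warning of class `phaselink_low_info` is raised when either
#'   side has zero informative SNPs.
#' @export
selectInformativeSnps <- function(signed, otherGenotypes, map,
                                  windowBp = 2e6) {
  if (signingCall(signed) != "signed")
    stopf("haplotypes must be signed before selecting informative SNPs")
  phs <- phasedSites(signed)
  tBlock <- phs$block[phs$site == signed@targetSite]
  s <- markerSites(map)
  cand <- phs[phs$block == tBlock & phs$site != signed@targetSite, , drop = FALSE]
  pos <- s$pos[cand$site]
  dist <- pos - signed@targetPos
  inWin <- abs(dist) <= windowBp & s$role[cand$site] == "marker"
  og <- otherGenotypes[cand$site]
  hom <- og %in% c("0/0", "1/1", "0|0", "1|1")
  keep <- inWin & hom
  riskAllele <- if (signed@riskHap == "A") cand$hapA else 1L - cand$hapA
  info <- data.frame(site = cand$site[keep], pos = pos[keep],
                     side = ifelse(dist[keep] < 0, "upstream", "downstream"),
                     distance = abs(dist[keep]),
                     riskAllele = as.integer(riskAllele[keep]),
                     otherGt = og[keep], stringsAsFactors = FALSE)
  info <- info[order(info$pos), ]
  rownames(info) <- NULL
  signed@informative <- info
  if (!all(c("upstream", "downstream") %in% info$side))
    warning(structure(class = c("phaselink_low_info", "warning", "condition"),
                      list(message = sprintf(
                        "no informative SNPs %s of the target for the %s parent",
                        setdiff(c("upstream", "downstream"), info$side)[1],
                        signed@parent), call = NULL)))
  signed
}

#' Summarize informative SNPs the way clinical workups report them
#'
#' @param signed A [SignedHaplotypePair-class] after
#'   [selectInformativeSnps()].
#' @return list with `counts` (upstream/downstream informative SNP counts,
#'   e.g. "29/33"-style) and `maxDistance` (bp to the farthest informative
#'   SNP on each side).
#' @export
informativeSummary <- function(signed) {
  info <- informativeSnps(signed)
  up <- info[info$side == "upstream", , drop = FALSE]
  down <- info[info$side == "downstream", , drop = FALSE]
  list(counts = c(upstream = nrow(up), downstream = nrow(down)),
       maxDistance = c(upstream = if (nrow(up)) max(up$distance) else 0,
                       downstream = if (nrow(down)) max(down$distance) else 0))
}

#' Count fragments spanning the target mutation
#'
#' @param fragments A [FragmentSet-class].
#' @param map The [MarkerMap-class].
#' @param targetSite Site index of the target (default: first target in the
#'   map).
#' @return Number of fragments whose interval covers the target position and
#'   that report an allele observation there.
#' @export
mutationSpanningReads <- function(fragments, map, targetSite = NULL) {
  if (is.null(targetSite)) targetSite <- targetIndices(map)[1]
  s <- markerSites(map)
  pos0 <- s$pos[targetSite] - 1  # 0-based
  fr <- fragmentTable(fragments)
  covers <- which(fr$chrom == s$chrom[targetSite] &
                  fr$start <= pos0 & fr$end > pos0)
  ob <- fragmentObservations(fragments)
  withObs <- unique(ob$fragment[ob$site == targetSite])
  length(intersect(covers, withObs))
}
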