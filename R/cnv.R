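# PGT-A copy-number arm: per-window log2 read-count ratio against a diploid
# reference panel, circular binary segmentation with a permutation test,
# segment merging, and integer / mosaic copy-number calling.

#' Normalize window counts to per-window log2 ratios
#'
#' Every sample (test and each reference) is scaled to a common total count;
#' per window the ratio of the scaled test count to the median scaled
#' reference count is taken and log2-transformed, and the resulting vector
#' is median-centred so that the diploid baseline sits at 0 (the median over
#' windows is robust to a single aneuploid chromosome, which would otherwise
#' bias every other window through the total-count scaling). Windows whose
#' raw median reference count falls below `minRefCount` are masked rather
#' than producing unstable ratios; a 0.5 pseudocount keeps zero-count
#' windows finite.
#'
#' @param track A [WindowCountTrack-class].
#' @param minRefCount Raw median reference count floor (default 10).
#' @return The track with `log2rr` and `masked` filled.
#' @export
computeLog2RR <- function(track, minRefCount = 10) {
  test <- track@test
  ref <- track@reference
  if (ncol(ref) < 1L) stopf("at least one reference sample is required")
  if (sum(test) == 0) stopf("test sample has zero total count")
  medRaw <- apply(ref, 1L, stats::median)
  masked <- medRaw < minRefCount
  totals <- c(sum(test), colSums(ref))
  target <- mean(totals)
  testS <- test * target / sum(test)
  refS <- sweep(ref, 2L, target / colSums(ref), `*`)
  medRef <- apply(refS, 1L, stats::median)
  l2 <- log2((testS + 0.5) / (medRef + 0.5))
  masked <- masked | !is.finite(l2)
  l2[masked] <- NA_real_
  if (all(masked)) stopf("all windows masked; reference panel too shallow")
  l2 <- l2 - stats::median(l2[!masked])
  # the segment caller works on segment MEANS, and the log of an
  # overdispersed count is left-skewed (mean < median), so re-centre on the
  # mean of baseline windows; chromosomes whose mean clearly departs from
  # baseline (whole-chromosome events) are excluded from the estimate
  sigma <- stats::mad(l2[!masked])
  if (sigma > 0) {
    # iterate: a chromosome-scale event near the exclusion boundary must
    # not leak into the baseline estimate, so exclude at 2 SE and re-centre
    # until stable
    for (it in 1:3) {
      ok <- !masked
      for (ch in unique(track@windows$chrom)) {
        sel <- track@windows$chrom == ch & !masked
        n <- sum(sel)
        if (n > 0L && abs(mean(l2[sel])) > 2 * sigma / sqrt(n))
          ok[track@windows$chrom == ch] <- FALSE
      }
      if (!any(ok)) ok <- !masked
      shift <- mean(l2[ok])
      l2 <- l2 - shift
      if (abs(shift) < 1e-6) break
    }
  }
  track@log2rr <- l2
  track@masked <- masked
  track
}

# max pooled-variance t statistic over all circular arc splits of x.
# Returns list(t, i, j): the arc is (i, j] in 1-based positions; cuts fall
# after index i and after index j.
cbsMaxT <- function(x, minWidth) {
  n <- length(x)
  S <- cumsum(x)
  tot <- S[n]
  TSS <- sum((x - tot / n)^2)
  pr <- cbsPairs(n, minWidth)
  if (length(pr$i) == 0L) return(list(t = -Inf, i = NA, j = NA))
  d <- S[pr$j] - ifelse(pr$i == 0L, 0, S[pmax(pr$i, 1L)])
  n1 <- pr$j - pr$i
  n2 <- n - n1
  m1 <- d / n1
  m2 <- (tot - d) / n2
  BSS <- n1 * n2 / n * (m1 - m2)^2
  s2 <- pmax((TSS - BSS) / max(n - 2L, 1L), 0)
  tt <- abs(m1 - m2) / sqrt(s2 * (1 / n1 + 1 / n2))
  tt[!is.finite(tt)] <- Inf
  k <- which.max(tt)
  list(t = tt[k], i = pr$i[k], j = pr$j[k])
}

# admissible (i, j) cut pairs: every resulting piece is empty or >= minWidth;
# cached per (n, minWidth) since the permutation loop reuses them heavily
.cbsPairCache <- new.env(parent = emptyenv())
cbsPairs <- function(n, minWidth) {
  key <- sprintf("%d_%d", n, minWidth)
  hit <- .cbsPairCache[[key]]
  if (!is.null(hit)) return(hit)
  ij <- expand.grid(i = 0:(n - 1L), j = 1:n)
  ij <- ij[ij$j > ij$i, , drop = FALSE]
  ok <- (ij$i == 0L | ij$i >= minWidth) &
        (ij$j - ij$i >= minWidth) &
        (ij$j == n | n - ij$j >= minWidth)
  ok <- ok & !(ij$i == 0L & ij$j == n)
  out <- list(i = ij$i[ok], j = ij$j[ok])
  .cbsPairCache[[key]] <- out
  out
}

#' Circular binary segmentation of a log2-ratio vector
#'
#' Classic CBS recursion: over the circularized sequence, find the arc
#' maximizing the pooled-variance t statistic between arc and complement;
#' accept the split if its permutation p-value (within-segment shuffles)
#' is below `alpha`; recurse on the resulting pieces.
#'
#' @param x Numeric vector of log2 ratios for one chromosome (no NAs).
#' @param alpha Permutation significance level (default 0.01).
#' @param nPerm Number of permutations (default 1000).
#' @param minWidth Minimum segment width in windows (default 3).
#' @param seed Integer seed making the permutation test deterministic.
#' @return Sorted integer vector of breakpoints; a breakpoint `k` means a
#'   change between positions `k` and `k + 1`.
#' @export
cbsSegment <- function(x, alpha = 0.01, nPerm = 1000L, minWidth = 3L,
                       seed = 1L) {
  if (anyNA(x)) stopf("mask NAs before segmentation")
  n <- length(x)
  cuts <- integer(0)
  withSeed(seed, {
    recurse <- function(lo, hi) {
      seg <- x[lo:hi]
      m <- length(seg)
      if (m < 2L * minWidth) return(invisible(NULL))
      if (stats::var(seg) == 0) return(invisible(NULL))
      best <- cbsMaxT(seg, minWidth)
      if (!is.finite(best$t)) return(invisible(NULL))
      exceed <- 0L
      for (b in seq_len(nPerm)) {
        tb <- cbsMaxT(sample(seg), minWidth)$t
        if (tb >= best$t) exceed <- exceed + 1L
      }
      p <- (1 + exceed) / (nPerm + 1)
      if (p >= alpha) return(invisible(NULL))
      i <- best$i; j <- best$j
      if (i > 0L) cuts <<- c(cuts, lo - 1L + i)
      if (j < m) cuts <<- c(cuts, lo - 1L + j)
      if (i > 0L) recurse(lo, lo - 1L + i)
      recurse(lo + i, lo - 1L + j)
      if (j < m) recurse(lo + j, hi)
      invisible(NULL)
    }
    recurse(1L, n)
  })
  sort(unique(cuts))
}

#' Invert a segment-mean log2 ratio to a mosaic fraction
#'
#' Under a linear mixture of diploid and abnormal cells, the expected depth
#' ratio of a single-copy event at an abnormal-cell fraction `f` is
#' `(2 + f)/2` (gain) or `(2 - f)/2` (loss), so
#' `f = 2 * 2^r - 2` (gain) and `f = 2 - 2 * 2^r` (loss), clamped to
#' `[0, 1]`.
#'
#' @param meanLog2rr Segment mean log2 ratio.
#' @param direction `"gain"` or `"loss"`.
#' @return Mosaic fraction in `[0, 1]`.
#' @export
estimateMosaicFraction <- function(meanLog2rr, direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  if (!is.finite(meanLog2rr)) stopf("segment mean must be finite")
  f <- if (direction == "gain") 2 * 2^meanLog2rr - 2 else 2 - 2 * 2^meanLog2rr
  min(max(f, 0), 1)
}

#' Merge segments and call copy-number states
#'
#' Adjacent segments whose means differ by less than `mergeTol` are pooled.
#' Each segment's mosaic fraction `f` is inverted from its mean log2 ratio;
#' `|f| < bands[1]` is normal (CN 2), `bands[1] <= f < bands[2]` is a mosaic
#' gain/loss reported as a percentage, and `f >= bands[2]` is a full event
#' with integer CN `round(2 * 2^mean)`. In addition to the banding, a
#' segment is only called abnormal when its mean deviates from the diploid
#' baseline by at least `zGate` standard errors (`zGate * sigma / sqrt(n)`,
#' with `sigma` the robust genome-wide per-window spread): the CBS
#' permutation test guards internal change-points but never tests a whole
#' chromosome against the baseline, so without this gate chromosome-level
#' noise would leak into the mosaic band.
#'
#' @param track A normalized [WindowCountTrack-class].
#' @param breakpoints Named list (per chromosome) of breakpoint indices in
#'   that chromosome's unmasked window sequence, as from [cbsSegment()].
#' @param mergeTol Mean-difference merge tolerance (default 0.1).
#' @param bands Mosaic banding thresholds (default `c(0.2, 0.8)`).
#' @param zGate Baseline-deviation gate in standard errors (default 3,
#'   matching the Z >= 3 convention of the ploidy screen).
#' @return data.frame of segments: `chrom`, `start`, `end` (0-based
#'   half-open window edges), `nWindows`, `meanLog2rr`, `cn`, `state`,
#'   `mosaicFraction`. Segments tile each chromosome.
#' @export
mergeAndCall <- function(track, breakpoints, mergeTol = 0.1,
                         bands = c(0.2, 0.8), zGate = 3) {
  w <- track@windows
  sigma <- stats::mad(track@log2rr[!track@masked], na.rm = TRUE)
  out <- list()
  for (ch in unique(w$chrom)) {
    idx <- which(w$chrom == ch & !track@masked)
    allIdx <- which(w$chrom == ch)
    if (!length(idx)) next
    l2 <- track@log2rr[idx]
    bp <- breakpoints[[ch]]
    if (is.null(bp)) bp <- integer(0)
    bounds <- c(0L, sort(bp), length(idx))
    segs <- data.frame(
      from = head(bounds, -1L) + 1L, to = bounds[-1L])
    segs$mean <- vapply(seq_len(nrow(segs)), function(k)
      mean(l2[segs$from[k]:segs$to[k]]), numeric(1))
    segs$n <- segs$to - segs$from + 1L
    # merge adjacent segments with closest means first
    while (nrow(segs) > 1L) {
      dif <- abs(diff(segs$mean))
      k <- which.min(dif)
      if (dif[k] >= mergeTol) break
      segs$mean[k] <- (segs$mean[k] * segs$n[k] + segs$mean[k + 1L] * segs$n[k + 1L]) /
        (segs$n[k] + segs$n[k + 1L])
      segs$to[k] <- segs$to[k + 1L]
      segs$n[k] <- segs$n[k] + segs$n[k + 1L]
      segs <- segs[-(k + 1L), , drop = FALSE]
    }
    # breakpoint bp coordinates: edges of the flanking unmasked windows;
    # chromosome ends come from the full tiling
    for (k in seq_len(nrow(segs))) {
      startBp <- if (k == 1L) w$start[allIdx[1L]] else w$start[idx[segs$from[k]]]
      endBp <- if (k == nrow(segs)) w$end[allIdx[length(allIdx)]]
               else w$end[idx[segs$to[k]]]
      r <- segs$mean[k]
      dir <- if (r >= 0) "gain" else "loss"
      f <- estimateMosaicFraction(r, dir)
      if (abs(r) < zGate * sigma / sqrt(segs$n[k])) f <- 0
      if (f < bands[1]) {
        state <- "normal"; cn <- 2L; frac <- 0
      } else if (f < bands[2]) {
        state <- paste0("mosaic-", dir); cn <- if (dir == "gain") 3L else 1L
        frac <- f
      } else {
        state <- dir
        cn <- max(0L, as.integer(round(2 * 2^r)))
        frac <- 1
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = startBp, end = endBp, nWindows = segs$n[k],
        meanLog2rr = r, cn = cn, state = state, mosaicFraction = frac,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ISCN-like display strings mirroring clinical CNV report notation
iscnFromSegments <- function(segments, windows) {
  abn <- segments[segments$state != "normal", , drop = FALSE]
  if (nrow(abn) == 0L) return("Euploid")
  chromSpan <- tapply(windows$end, windows$chrom, max)
  chromStart <- tapply(windows$start, windows$chrom, min)
  vapply(seq_len(nrow(abn)), function(k) {
    s <- abn[k, ]
    whole <- s$start <= chromStart[[s$chrom]] && s$end >= chromSpan[[s$chrom]]
    chName <- sub("^chr", "", s$chrom)
    pct <- sprintf(" (%d%%)", round(100 * s$mosaicFraction))
    if (whole) {
      switch(s$state,
        gain = sprintf("+%s", chName),
        loss = sprintf("-%s", chName),
        `mosaic-gain` = sprintf("+(mosaic)(%s)%s", chName, pct),
        `mosaic-loss` = sprintf("-(mosaic)(%s)%s", chName, pct))
    } else {
      coords <- sprintf("(%d-%d)", s$start + 1L, s$end)
      switch(s$state,
        gain = sprintf("dup(%s)%sx%d", chName, coords, s$cn),
        loss = sprintf("del(%s)%sx%d", chName, coords, s$cn),
        `mosaic-gain` = sprintf("dup(mosaic)(%s)%sx3%s", chName, coords, pct),
        `mosaic-loss` = sprintf("del(mosaic)(%s)%sx1%s", chName, coords, pct))
    }
  }, character(1))
}

#' Run the full copy-number analysis for one embryo
#'
#' Normalization ([computeLog2RR()]), per-chromosome CBS ([cbsSegment()]),
#' merging and state calling ([mergeAndCall()]).
#'
#' @param track A [WindowCountTrack-class].
#' @param alpha,nPerm,minWidth CBS parameters.
#' @param mergeTol,bands Calling parameters (see [mergeAndCall()]).
#' @param minRefCount Reference-median mask floor.
#' @param seed Integer seed for the permutation tests.
#' @return A [CNVResult-class].
#' @export
runCnv <- function(track, alpha = 0.01, nPerm = 1000L, minWidth = 3L,
                   mergeTol = 0.1, bands = c(0.2, 0.8), minRefCount = 10,
                   seed = 1L) {
  track <- computeLog2RR(track, minRefCount = minRefCount)
  w <- track@windows
  chroms <- unique(w$chrom)
  subSeeds <- deriveSeeds(seed, length(chroms))
  bps <- list()
  for (k in seq_along(chroms)) {
    idx <- which(w$chrom == chroms[k] & !track@masked)
    if (length(idx) < 2L * minWidth) { bps[[chroms[k]]] <- integer(0); next }
    bps[[chroms[k]]] <- cbsSegment(track@log2rr[idx], alpha = alpha,
                                   nPerm = nPerm, minWidth = minWidth,
                                   seed = subSeeds[k])
  }
  segments <- mergeAndCall(track, bps, mergeTol = mergeTol, bands = bands)
  new("CNVResult", track = track, segments = segments,
      iscn = iscnFromSegments(segments, w))
}
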