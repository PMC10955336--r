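# Runs-of-homozygosity detection: windowed heterozygosity of the test
# embryo against the reference panel, log10 ratio thresholded at -1 (a
# ten-fold heterozygosity reduction), with copy-number exclusion - a window
# whose het loss is explained by a deletion is not ROH.

#' Per-window heterozygous-site fraction
#'
#' @param embryo An [EmbryoGenotypes-class].
#' @param windows Window grid data.frame (`chrom`, `start`, `end`, 0-based
#'   half-open), e.g. from [makeWindows()].
#' @param depthFloor Minimum depth for a callable site (default 8).
#' @param minSites Minimum callable sites per window; windows below it are
#'   masked (default 20).
#' @return data.frame `chrom`, `start`, `end`, `callable`, `het`, `F`
#'   (het / callable; NA when masked).
#' @export
windowHetFraction <- function(embryo, windows, depthFloor = 8, minSites = 20L) {
  calls <- genotypeCalls(embryo)
  ok <- calls$dp >= depthFloor & calls$gt != "./."
  het <- ok & calls$gt == "0/1"
  out <- windows
  out$callable <- 0L
  out$het <- 0L
  for (ch in unique(windows$chrom)) {
    wsel <- which(windows$chrom == ch)
    csel <- which(calls$chrom == ch & ok)
    if (!length(csel)) next
    # 0-based site coordinate against half-open windows
    bin <- findInterval(calls$pos[csel] - 1, windows$start[wsel])
    valid <- bin >= 1L & calls$pos[csel] - 1 < windows$end[wsel][pmax(bin, 1L)]
    tabAll <- tabulate(bin[valid], nbins = length(wsel))
    tabHet <- tabulate(bin[valid & het[csel]], nbins = length(wsel))
    out$callable[wsel] <- tabAll
    out$het[wsel] <- tabHet
  }
  out$F <- ifelse(out$callable >= minSites, out$het / out$callable, NA_real_)
  out
}

#' Panel median heterozygosity per window
#'
#' @param panel List of diploid [EmbryoGenotypes-class] objects.
#' @param windows Window grid.
#' @param depthFloor,minSites Passed to [windowHetFraction()].
#' @return Numeric vector: per-window median `F` across the panel.
#' @export
panelHetFraction <- function(panel, windows, depthFloor = 8, minSites = 20L) {
  fs <- sapply(panel, function(e)
    windowHetFraction(e, windows, depthFloor, minSites)$F)
  apply(fs, 1L, stats::median, na.rm = TRUE)
}

#' Call runs of homozygosity
#'
#' Per window, `logRatio = log10((F1 + eps) / (F2 + eps))` with the
#' pseudocount `eps = 1 / (2 * callable sites)` guarding `log(0)`. A window
#' is an ROH candidate iff `logRatio <= -1` and it does not overlap a
#' non-normal copy-number segment; adjacent candidate windows merge into
#' regions.
#'
#' @param f1 Test-track data.frame from [windowHetFraction()].
#' @param f2 Reference per-window het fraction (same grid), e.g. from
#'   [panelHetFraction()].
#' @param cnvSegments Segment data.frame from [mergeAndCall()] /
#'   [cnvSegments()]; may be NULL when no CNV analysis is available.
#' @param threshold Log10-ratio threshold (default -1).
#' @return An [ROHResult-class].
#' @export
rohCalls <- function(f1, f2, cnvSegments = NULL, threshold = -1) {
  if (length(f2) != nrow(f1)) stopf("F1 and F2 are not on the same window grid")
  eps <- ifelse(f1$callable > 0, 1 / (2 * f1$callable), NA_real_)
  logRatio <- log10((f1$F + eps) / (f2 + eps))
  cnvOverlap <- rep(FALSE, nrow(f1))
  if (!is.null(cnvSegments) && nrow(cnvSegments)) {
    abn <- cnvSegments[cnvSegments$state != "normal", , drop = FALSE]
    if (nrow(abn)) {
      wg <- GenomicRanges::GRanges(f1$chrom,
              IRanges::IRanges(start = f1$start + 1L, end = f1$end))
      sg <- GenomicRanges::GRanges(abn$chrom,
              IRanges::IRanges(start = abn$start + 1L, end = abn$end))
      hits <- GenomicRanges::findOverlaps(wg, sg)
      cnvOverlap[unique(S4Vectors::queryHits(hits))] <- TRUE
    }
  }
  callable <- !is.na(f1$F) & !is.na(f2) & !is.na(logRatio)
  isRoh <- callable & logRatio <= threshold & !cnvOverlap
  win <- data.frame(chrom = f1$chrom, start = f1$start, end = f1$end,
                    F1 = f1$F, F2 = f2, logRatio = logRatio,
                    cnvOverlap = cnvOverlap, isRoh = isRoh,
                    callable = callable, stringsAsFactors = FALSE)
  regions <- list()
  for (ch in unique(win$chrom)) {
    sel <- which(win$chrom == ch)
    r <- rle(win$isRoh[sel])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      idx <- sel[starts[k]:ends[k]]
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch, start = win$start[idx[1]], end = win$end[idx[length(idx)]],
        nWindows = length(idx), meanLogRatio = mean(win$logRatio[idx]),
        stringsAsFactors = FALSE)
    }
  }
  regions <- if (length(regions)) do.call(rbind, regions)
             else data.frame(chrom = character(0), start = numeric(0),
                             end = numeric(0), nWindows = integer(0),
                             meanLogRatio = numeric(0))
  new("ROHResult", windows = win, regions = regions)
}
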