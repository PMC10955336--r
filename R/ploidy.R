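# Chromosome-level ploidy screen: heterozygous-SNP proportion and B-allele
# frequency deviation per chromosome, standardized against a panel of
# diploid samples. Depth-only copy-number analysis cannot see genome-wide
# ploidy changes (a triploid is "euploid" in relative depth); the genotype
# channel can: haploids lose heterozygous calls, triploids shift het-site
# BAF towards 1/3 and 2/3.

#' Per-chromosome heterozygosity and BAF statistics
#'
#' @param embryo An [EmbryoGenotypes-class].
#' @param depthFloor Minimum depth for a site to be callable (default 8).
#' @param minCallable Minimum callable sites per chromosome; chromosomes
#'   below it are marked uninformative (default 50).
#' @return data.frame `chrom`, `callable`, `hetProp` (het calls / callable),
#'   `bafDev` (mean `|BAF - 0.5|` over het calls; NA when no het calls),
#'   `informative`.
#' @export
chromStats <- function(embryo, depthFloor = 8, minCallable = 50L) {
  calls <- genotypeCalls(embryo)
  ok <- calls$dp >= depthFloor & calls$gt != "./."
  out <- lapply(unique(calls$chrom), function(ch) {
    sel <- ok & calls$chrom == ch
    callable <- sum(sel)
    het <- sel & calls$gt == "0/1"
    data.frame(chrom = ch, callable = callable,
               hetProp = if (callable) sum(het) / callable else NA_real_,
               bafDev = if (any(het)) mean(abs(calls$baf[het] - 0.5)) else NA_real_,
               informative = callable >= minCallable,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Reference-panel summary of chromosome statistics
#'
#' @param panel List of diploid [EmbryoGenotypes-class] objects (>= 10
#'   recommended).
#' @param depthFloor,minCallable Passed to [chromStats()].
#' @return data.frame `chrom`, `muHet`, `sdHet`, `muBaf`, `sdBaf`, `n`.
#' @export
panelStats <- function(panel, depthFloor = 8, minCallable = 50L) {
  if (length(panel) < 2L) stopf("the reference panel needs >= 2 samples")
  st <- lapply(panel, chromStats, depthFloor = depthFloor,
               minCallable = minCallable)
  chroms <- st[[1]]$chrom
  het <- sapply(st, function(s) s$hetProp[match(chroms, s$chrom)])
  baf <- sapply(st, function(s) s$bafDev[match(chroms, s$chrom)])
  data.frame(chrom = chroms,
             muHet = rowMeans(het, na.rm = TRUE),
             sdHet = apply(het, 1L, stats::sd, na.rm = TRUE),
             muBaf = rowMeans(baf, na.rm = TRUE),
             sdBaf = apply(baf, 1L, stats::sd, na.rm = TRUE),
             n = length(panel), stringsAsFactors = FALSE)
}

#' Chromosome Z scores and the genome-wide ploidy call
#'
#' Standardizes each chromosome's het proportion and BAF deviation against
#' the panel; a chromosome is flagged when
#' `z = max(|z_het|, |z_baf|) >= threshold` (default 3). The genome-wide
#' call requires at least `genomeFrac` of informative autosomes flagged in a
#' consistent direction: depressed heterozygosity means haploid-suspect,
#' elevated BAF deviation (het BAF pulled towards 1/3 and 2/3, median
#' chromosome `bafDev >= 0.12`) means triploid-suspect; a genome-wide but
#' direction-inconsistent pattern is abnormal-unspecified. One aneuploid
#' chromosome can never trigger a ploidy call.
#'
#' @param stats Test-sample statistics from [chromStats()].
#' @param panel Panel summary from [panelStats()].
#' @param threshold Z threshold (default 3).
#' @param genomeFrac Fraction of autosomes required for a genome-wide call
#'   (default 0.8).
#' @return A [PloidyReport-class].
#' @export
zScores <- function(stats, panel, threshold = 3, genomeFrac = 0.8) {
  m <- match(stats$chrom, panel$chrom)
  if (anyNA(m)) stopf("panel is missing chromosomes present in the test sample")
  if (any(panel$sdHet[m] == 0, na.rm = TRUE) ||
      any(panel$sdBaf[m] == 0, na.rm = TRUE))
    stopf("panel standard deviation is zero; use a larger or noisier reference panel")
  zHet <- (stats$hetProp - panel$muHet[m]) / panel$sdHet[m]
  zBaf <- (stats$bafDev - panel$muBaf[m]) / panel$sdBaf[m]
  z <- pmax(abs(zHet), abs(zBaf), na.rm = TRUE)
  z[is.na(zHet) & is.na(zBaf)] <- NA_real_
  flagged <- !is.na(z) & z >= threshold & stats$informative
  chroms <- data.frame(stats, zHet = zHet, zBaf = zBaf, z = z,
                       flagged = flagged, stringsAsFactors = FALSE)
  inf <- which(stats$informative)
  frac <- if (length(inf)) mean(flagged[inf]) else 0
  call <- "normal"
  karyotype <- "46,XN"
  if (frac >= genomeFrac) {
    hetDown <- !is.na(zHet) & zHet <= -threshold
    bafUp <- !is.na(zBaf) & zBaf >= threshold
    medBaf <- stats::median(stats$bafDev[inf], na.rm = TRUE)
    if (mean(hetDown[inf]) >= genomeFrac) {
      call <- "haploid-suspect"; karyotype <- "23,XN"
    } else if (mean(bafUp[inf]) >= genomeFrac && !is.na(medBaf) &&
               medBaf >= 0.12) {
      call <- "triploid-suspect"; karyotype <- "69,XNN"
    } else {
      call <- "abnormal-unspecified"; karyotype <- "abnormal"
    }
  }
  new("PloidyReport", chromosomes = chroms, call = call,
      karyotype = karyotype, threshold = threshold)
}
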