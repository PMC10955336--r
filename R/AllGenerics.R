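# Accessor generics and show methods. Slot access from user code should go
# through these.

#' @rdname MarkerMap-class
#' @param object,x An object of the documented class.
#' @export
setGeneric("markerSites", function(x) standardGeneric("markerSites"))

#' @rdname MarkerMap-class
#' @export
setMethod("markerSites", "MarkerMap", function(x) x@sites)

#' @rdname MarkerMap-class
#' @export
setGeneric("mapRegions", function(x) standardGeneric("mapRegions"))

#' @rdname MarkerMap-class
#' @export
setMethod("mapRegions", "MarkerMap", function(x) x@regions)

#' @rdname MarkerMap-class
#' @export
setGeneric("targetSpec", function(x) standardGeneric("targetSpec"))

#' @rdname MarkerMap-class
#' @export
setMethod("targetSpec", "MarkerMap", function(x) x@target)

#' Indices of target sites in a marker map
#' @param x A [MarkerMap-class].
#' @return Integer vector of site indices with role `target`.
#' @export
targetIndices <- function(x) which(markerSites(x)$role == "target")

#' @rdname ParentalTruth-class
#' @param x A [ParentalTruth-class].
#' @export
setGeneric("truthHaplotypes", function(x) standardGeneric("truthHaplotypes"))

#' @rdname ParentalTruth-class
#' @export
setMethod("truthHaplotypes", "ParentalTruth", function(x) x@haplotypes)

#' @rdname ParentalTruth-class
#' @export
setGeneric("truthGenotypes", function(x) standardGeneric("truthGenotypes"))

#' @rdname ParentalTruth-class
#' @export
setMethod("truthGenotypes", "ParentalTruth", function(x) x@genotypes)

#' @rdname ParentalTruth-class
#' @export
setGeneric("truthMap", function(x) standardGeneric("truthMap"))

#' @rdname ParentalTruth-class
#' @export
setMethod("truthMap", "ParentalTruth", function(x) x@map)

#' @rdname FragmentSet-class
#' @param x A [FragmentSet-class].
#' @export
setGeneric("fragmentTable", function(x) standardGeneric("fragmentTable"))

#' @rdname FragmentSet-class
#' @export
setMethod("fragmentTable", "FragmentSet", function(x) x@fragments)

#' @rdname FragmentSet-class
#' @export
setGeneric("fragmentObservations", function(x) standardGeneric("fragmentObservations"))

#' @rdname FragmentSet-class
#' @export
setMethod("fragmentObservations", "FragmentSet", function(x) x@observations)

#' @rdname EmbryoGenotypes-class
#' @param x An [EmbryoGenotypes-class].
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @rdname EmbryoGenotypes-class
#' @export
setMethod("genotypeCalls", "EmbryoGenotypes", function(x) x@calls)

#' @rdname EmbryoGenotypes-class
#' @export
setGeneric("embryoId", function(x) standardGeneric("embryoId"))

#' @rdname EmbryoGenotypes-class
#' @export
setMethod("embryoId", "EmbryoGenotypes", function(x) x@embryoId)

#' @rdname LinkageCall-class
#' @export
setMethod("embryoId", "LinkageCall", function(x) x@embryoId)

#' @rdname EmbryoReport-class
#' @export
setMethod("embryoId", "EmbryoReport", function(x) x@embryoId)

#' @rdname PhasedHaplotypes-class
#' @param x A [PhasedHaplotypes-class] or [SignedHaplotypePair-class].
#' @export
setGeneric("phasedSites", function(x) standardGeneric("phasedSites"))

#' @rdname PhasedHaplotypes-class
#' @export
setMethod("phasedSites", "PhasedHaplotypes", function(x) x@sites)

#' @rdname SignedHaplotypePair-class
#' @export
setMethod("phasedSites", "SignedHaplotypePair", function(x) x@phased@sites)

#' @rdname SignedHaplotypePair-class
#' @param x A [SignedHaplotypePair-class].
#' @export
setGeneric("riskHaplotype", function(x) standardGeneric("riskHaplotype"))

#' @rdname SignedHaplotypePair-class
#' @export
setMethod("riskHaplotype", "SignedHaplotypePair", function(x) x@riskHap)

#' @rdname SignedHaplotypePair-class
#' @export
setGeneric("signingCall", function(x) standardGeneric("signingCall"))

#' @rdname SignedHaplotypePair-class
#' @export
setMethod("signingCall", "SignedHaplotypePair", function(x) x@call)

#' @rdname SignedHaplotypePair-class
#' @export
setGeneric("informativeSnps", function(x) standardGeneric("informativeSnps"))

#' @rdname SignedHaplotypePair-class
#' @export
setMethod("informativeSnps", "SignedHaplotypePair", function(x) x@informative)

#' @rdname SignedHaplotypePair-class
#' @export
setGeneric("phasedSpan", function(x) standardGeneric("phasedSpan"))

#' @rdname SignedHaplotypePair-class
#' @export
setMethod("phasedSpan", "SignedHaplotypePair",
          function(x) c(upstream = x@spanUp, downstream = x@spanDown))

#' @rdname CNVResult-class
#' @param x A [CNVResult-class].
#' @export
setGeneric("cnvSegments", function(x) standardGeneric("cnvSegments"))

#' @rdname CNVResult-class
#' @export
setMethod("cnvSegments", "CNVResult", function(x) x@segments)

#' @rdname CNVResult-class
#' @export
setGeneric("iscnStrings", function(x) standardGeneric("iscnStrings"))

#' @rdname CNVResult-class
#' @export
setMethod("iscnStrings", "CNVResult", function(x) x@iscn)

#' Copy-number segments as a GRanges
#' @param x A [CNVResult-class].
#' @return A [GenomicRanges::GRanges] with segment metadata columns.
#' @export
segmentsGRanges <- function(x) {
  seg <- cnvSegments(x)
  GenomicRanges::GRanges(seg$chrom,
    IRanges::IRanges(start = seg$start + 1L, end = seg$end),
    nWindows = seg$nWindows, meanLog2rr = seg$meanLog2rr,
    cn = seg$cn, state = seg$state, mosaicFraction = seg$mosaicFraction)
}

#' @rdname PloidyReport-class
#' @param x A [PloidyReport-class].
#' @export
setGeneric("ploidyCall", function(x) standardGeneric("ploidyCall"))

#' @rdname PloidyReport-class
#' @export
setMethod("ploidyCall", "PloidyReport", function(x) x@call)

#' @rdname PloidyReport-class
#' @export
setGeneric("chromosomeStats", function(x) standardGeneric("chromosomeStats"))

#' @rdname PloidyReport-class
#' @export
setMethod("chromosomeStats", "PloidyReport", function(x) x@chromosomes)

#' @rdname ROHResult-class
#' @param x A [ROHResult-class].
#' @export
setGeneric("rohRegions", function(x) standardGeneric("rohRegions"))

#' @rdname ROHResult-class
#' @export
setMethod("rohRegions", "ROHResult", function(x) x@regions)

#' @rdname ROHResult-class
#' @export
setGeneric("rohWindows", function(x) standardGeneric("rohWindows"))

#' @rdname ROHResult-class
#' @export
setMethod("rohWindows", "ROHResult", function(x) x@windows)

#' @rdname LinkageCall-class
#' @param x A [LinkageCall-class].
#' @export
setGeneric("linkageStatus", function(x) standardGeneric("linkageStatus"))

#' @rdname LinkageCall-class
#' @export
setMethod("linkageStatus", "LinkageCall", function(x) x@status)

#' @rdname EmbryoReport-class
#' @param x An [EmbryoReport-class].
#' @export
setGeneric("reportFlags", function(x) standardGeneric("reportFlags"))

#' @rdname EmbryoReport-class
#' @export
setMethod("reportFlags", "EmbryoReport", function(x) x@flags)

setMethod("show", "MarkerMap", function(object) {
  s <- object@sites
  cat(sprintf("MarkerMap: %d sites (%d markers, %d targets) on %s\n",
              nrow(s), sum(s$role == "marker"), sum(s$role == "target"),
              paste(object@regions$chrom, collapse = ", ")))
})

setMethod("show", "FragmentSet", function(object) {
  cat(sprintf("FragmentSet (%s): %d fragments, %d allele observations\n",
              object@parent, nrow(object@fragments), nrow(object@observations)))
})

setMethod("show", "PhasedHaplotypes", function(object) {
  s <- object@sites
  cat(sprintf("PhasedHaplotypes: %d sites in %d block(s), from %d fragments\n",
              nrow(s), length(unique(s$block)), object@nFragments))
})

setMethod("show", "SignedHaplotypePair", function(object) {
  cat(sprintf("SignedHaplotypePair (%s): %s", object@parent, object@call))
  if (object@call == "signed")
    cat(sprintf(", risk = hap %s (consistency %.2f, %d spanning fragments)",
                object@riskHap, object@consistency, object@spanningReads))
  cat(sprintf("\n  phased span: %.0f bp upstream / %.0f bp downstream; %d informative SNPs\n",
              object@spanUp, object@spanDown, nrow(object@informative)))
})

setMethod("show", "CNVResult", function(object) {
  cat(sprintf("CNVResult: %d segments; %s\n", nrow(object@segments),
              paste(object@iscn, collapse = "; ")))
})

setMethod("show", "PloidyReport", function(object) {
  cat(sprintf("PloidyReport: %s (%s); %d/%d chromosomes flagged at |Z| >= %g\n",
              object@call, object@karyotype,
              sum(object@chromosomes$flagged, na.rm = TRUE),
              nrow(object@chromosomes), object@threshold))
})

setMethod("show", "ROHResult", function(object) {
  cat(sprintf("ROHResult: %d candidate region(s) over %d windows\n",
              nrow(object@regions), nrow(object@windows)))
})

setMethod("show", "LinkageCall", function(object) {
  cat(sprintf("LinkageCall [%s]: %s (%s), confidence %.2f\n",
              object@embryoId, object@status, object@detail, object@confidence))
})

setMethod("show", "EmbryoReport", function(object) {
  cat(sprintf("EmbryoReport [%s]\n", object@embryoId))
  st <- if (is.null(object@linkage)) "-" else object@linkage@status
  cat(sprintf("  PGT-M: %s | PGT-A: %s | ploidy: %s | ROH regions: %d\n",
              st, paste(object@cnv@iscn, collapse = "; "),
              object@ploidy@call, nrow(object@roh@regions)))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})
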