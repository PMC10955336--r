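#' @import methods
NULL

#' MarkerMap: ordered marker and target sites on one or more regions
#'
#' Holds the heterozygous SNP/indel marker scaffold used for phasing and
#' linkage, plus zero or more designated pathogenic target sites. Variant
#' positions are 1-based (VCF convention); region bounds are 1-based
#' inclusive.
#'
#' @slot regions data.frame with columns `chrom`, `start`, `end`.
#' @slot sites data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `var_type` (`SNV`, `INS`, `DEL`), `role` (`marker`, `target`), `maf`.
#' @slot target A [PathogenicTarget-class] or `NULL`.
#' @export
setClass("MarkerMap",
  representation(regions = "data.frame", sites = "data.frame", target = "ANY"))

setValidity("MarkerMap", function(object) {
  s <- object@sites
  need <- c("chrom", "pos", "ref", "alt", "var_type", "role", "maf")
  if (!all(need %in% names(s))) return("sites is missing required columns")
  if (nrow(s) == 0L) return("empty site table")
  if (any(s$pos < 1)) return("positions must be >= 1")
  if (any(s$ref == s$alt)) return("ref and alt must differ")
  if (!all(s$var_type %in% c("SNV", "INS", "DEL")))
    return("var_type must be SNV, INS or DEL")
  snv <- s$var_type == "SNV"
  if (any(nchar(s$ref[snv]) != 1L | nchar(s$alt[snv]) != 1L))
    return("SNV alleles must have length 1")
  indel <- !snv
  if (any(pmax(nchar(s$ref[indel]), nchar(s$alt[indel])) > 51L))
    return("indels are limited to 50 bp; larger events are CNV territory")
  if (!all(s$role %in% c("marker", "target"))) return("bad site role")
  for (ch in unique(s$chrom)) {
    p <- s$pos[s$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      return("sites must be strictly increasing within each chromosome")
  }
  TRUE
})

#' PathogenicTarget: the variant(s) whose transmission is under test
#'
#' @slot site One-row data.frame (`chrom`, `pos`, `ref`, `alt`, `var_type`)
#'   for the primary pathogenic variant.
#' @slot parent `"maternal"` or `"paternal"`: the carrier of `site`.
#' @slot inheritance `"AD"` or `"AR"`.
#' @slot partnerSite Zero- or one-row data.frame: a second pathogenic allele
#'   carried by the other parent (same variant for classic AR, a different
#'   one for compound heterozygosity). Requires `inheritance == "AR"`.
#' @export
setClass("PathogenicTarget",
  representation(site = "data.frame", parent = "character",
                 inheritance = "character", partnerSite = "data.frame"))

setValidity("PathogenicTarget", function(object) {
  if (!object@parent %in% c("maternal", "paternal")) return("bad parent label")
  if (!object@inheritance %in% c("AD", "AR")) return("inheritance must be AD or AR")
  if (nrow(object@partnerSite) > 0L && object@inheritance != "AR")
    return("a partner allele on the other parent implies AR inheritance")
  TRUE
})

#' ParentalTruth: simulated phased parental genomes
#'
#' @slot map The [MarkerMap-class] the truth is defined on.
#' @slot haplotypes list(maternal=, paternal=) of 2 x n 0/1 allele matrices
#'   (row 1 = haplotype 1, row 2 = haplotype 2).
#' @slot genotypes list(maternal=, paternal=) of unphased genotype strings.
#' @export
setClass("ParentalTruth",
  representation(map = "MarkerMap", haplotypes = "list", genotypes = "list"))

#' FragmentSet: barcoded linked-read molecule observations
#'
#' Fragment intervals are 0-based half-open; `observations` rows point into
#' the marker map by site index.
#'
#' @slot parent Parent label the fragments were drawn from.
#' @slot fragments data.frame `barcode`, `chrom`, `start`, `end`, `hap`
#'   (source haplotype, NA when unknown/real data).
#' @slot observations data.frame `fragment` (row index into `fragments`),
#'   `site` (index into the map), `allele` (0/1), `qual`.
#' @slot nSites Number of sites in the underlying map.
#' @export
setClass("FragmentSet",
  representation(parent = "character", fragments = "data.frame",
                 observations = "data.frame", nSites = "integer"))

setValidity("FragmentSet", function(object) {
  ob <- object@observations
  if (nrow(ob) > 0L) {
    if (any(!ob$allele %in% c(0L, 1L))) return("allele codes must be 0/1")
    if (any(ob$fragment < 1L | ob$fragment > nrow(object@fragments)))
      return("observation points to a missing fragment")
    sp <- split(ob$site, ob$fragment)
    if (any(vapply(sp, function(x) is.unsorted(x, strictly = TRUE), logical(1))))
      return("site indices must be strictly increasing within a fragment")
  }
  TRUE
})

#' EmbryoTruth: the simulated state of one embryo
#'
#' @slot map Marker map.
#' @slot transmitted list(maternal=, paternal=) of per-site transmitted
#'   haplotype labels (1 or 2).
#' @slot crossovers data.frame `parent`, `chrom`, `pos`.
#' @slot ploidy One of `diploid`, `haploid`, `triploid`, `trisomy`,
#'   `monosomy`, `segmental`.
#' @slot ploidyChrom Chromosome of a trisomy/monosomy/segmental event.
#' @slot segment data.frame `chrom`, `start`, `end`, `direction` for
#'   segmental events (0-based half-open).
#' @slot mosaicFraction Abnormal-cell fraction in (0, 1]; 1 for non-mosaic.
#' @slot rohRegions data.frame `chrom`, `start`, `end` forced homozygous.
#' @slot extra list(parent=, hap=) describing the additional copy of a
#'   triploid/trisomic genome.
#' @export
setClass("EmbryoTruth",
  representation(map = "MarkerMap", transmitted = "list",
                 crossovers = "data.frame", ploidy = "character",
                 ploidyChrom = "character", segment = "data.frame",
                 mosaicFraction = "numeric", rohRegions = "data.frame",
                 extra = "list"))

setValidity("EmbryoTruth", function(object) {
  if (!object@ploidy %in% c("diploid", "haploid", "triploid", "trisomy",
                            "monosomy", "segmental"))
    return("unknown ploidy state")
  f <- object@mosaicFraction
  if (length(f) != 1L || is.na(f) || f <= 0 || f > 1)
    return("mosaicFraction must be in (0, 1]")
  if (f < 1 && !object@ploidy %in% c("trisomy", "monosomy", "segmental"))
    return("mosaicFraction < 1 is only supported for copy-number states")
  TRUE
})

#' EmbryoGenotypes: post-MDA genotype calls for one embryo
#'
#' @slot embryoId Embryo identifier.
#' @slot map Marker map the calls are indexed against.
#' @slot calls data.frame `site`, `chrom`, `pos`, `gt`, `dp`, `altDp`, `baf`.
#' @export
setClass("EmbryoGenotypes",
  representation(embryoId = "character", map = "MarkerMap",
                 calls = "data.frame"))

#' PhasedHaplotypes: block-phased heterozygous sites for one parent
#'
#' Haplotype A allele is reported per site; haplotype B is its complement.
#' Orientation within a block is arbitrary until signed.
#'
#' @slot sites data.frame `site`, `block`, `hapA`, `conf` (fraction of
#'   covering fragments consistent with the phase).
#' @slot nFragments Number of fragments used.
#' @export
setClass("PhasedHaplotypes",
  representation(sites = "data.frame", nFragments = "integer"))

setValidity("PhasedHaplotypes", function(object) {
  s <- object@sites
  if (nrow(s) > 0L && any(!s$hapA %in% c(0L, 1L))) return("hapA must be 0/1")
  TRUE
})

#' SignedHaplotypePair: risk / non-risk labelled parental haplotypes
#'
#' @slot parent Parent label.
#' @slot phased The underlying [PhasedHaplotypes-class].
#' @slot targetSite Site index of the pathogenic variant.
#' @slot targetPos Its 1-based position.
#' @slot call `"signed"` or `"nocall"`.
#' @slot riskHap `"A"` or `"B"`: which phased haplotype carries the target
#'   alt allele (NA when nocall).
#' @slot consistency Fraction of target-spanning fragments consistent with
#'   the assigned phase at the target.
#' @slot spanningReads Number of fragments spanning the target with an
#'   allele observation there.
#' @slot spanUp,spanDown Phased extent (bp) of the target's block on each
#'   side of the target.
#' @slot informative data.frame of informative SNPs (filled by
#'   [selectInformativeSnps()]): `site`, `pos`, `side`, `distance`,
#'   `riskAllele`, `otherGt`.
#' @export
setClass("SignedHaplotypePair",
  representation(parent = "character", phased = "PhasedHaplotypes",
                 targetSite = "integer", targetPos = "numeric",
                 call = "character", riskHap = "character",
                 consistency = "numeric", spanningReads = "integer",
                 spanUp = "numeric", spanDown = "numeric",
                 informative = "data.frame"))

#' WindowCountTrack: per-window read counts for PGT-A
#'
#' Windows are 0-based half-open on a fixed grid shared between the test
#' sample and the reference panel.
#'
#' @slot windows data.frame `chrom`, `start`, `end`.
#' @slot test Numeric test-sample counts, one per window.
#' @slot reference Windows x samples matrix of reference counts.
#' @slot log2rr Per-window log2 ratio (filled by [computeLog2RR()]).
#' @slot masked Logical; windows excluded from analysis.
#' @export
setClass("WindowCountTrack",
  representation(windows = "data.frame", test = "numeric",
                 reference = "matrix", log2rr = "numeric", masked = "logical"))

setValidity("WindowCountTrack", function(object) {
  n <- nrow(object@windows)
  if (length(object@test) != n) return("test counts do not match window grid")
  if (nrow(object@reference) != n) return("reference panel does not match window grid")
  if (any(object@test < 0) || any(object@reference < 0)) return("counts must be >= 0")
  TRUE
})

#' CNVResult: segmented copy-number calls for one embryo
#'
#' @slot track The normalized [WindowCountTrack-class].
#' @slot segments data.frame `chrom`, `start`, `end`, `nWindows`,
#'   `meanLog2rr`, `cn`, `state`, `mosaicFraction`.
#' @slot iscn Character vector of ISCN-like abnormality strings
#'   (`"Euploid"` when none).
#' @export
setClass("CNVResult",
  representation(track = "WindowCountTrack", segments = "data.frame",
                 iscn = "character"))

#' PloidyReport: chromosome-level Z-score screen for ploidy abnormalities
#'
#' @slot chromosomes data.frame `chrom`, `callable`, `hetProp`, `bafDev`,
#'   `zHet`, `zBaf`, `z`, `flagged`, `informative`.
#' @slot call `normal`, `haploid-suspect`, `triploid-suspect` or
#'   `abnormal-unspecified`.
#' @slot karyotype Display string (`"69,XNN"` for triploid-suspect).
#' @slot threshold The Z threshold used (default 3).
#' @export
setClass("PloidyReport",
  representation(chromosomes = "data.frame", call = "character",
                 karyotype = "character", threshold = "numeric"))

#' ROHResult: runs-of-homozygosity calls
#'
#' @slot windows data.frame `chrom`, `start`, `end`, `F1`, `F2`, `logRatio`,
#'   `cnvOverlap`, `isRoh`, `callable`.
#' @slot regions Merged candidate regions: `chrom`, `start`, `end`,
#'   `nWindows`, `meanLogRatio`.
#' @export
setClass("ROHResult",
  representation(windows = "data.frame", regions = "data.frame"))

#' LinkageCall: the PGT-M readout for one embryo
#'
#' @slot embryoId Embryo identifier.
#' @slot perParent Named list (per analysed carrier parent) with elements
#'   `votes` (per-site vote table), `votesRisk`, `votesNonrisk`,
#'   `crossovers`, `label`, `confidence`, `flags`, `mendelErrors`.
#' @slot status `unaffected`, `carrier(mat)`, `carrier(pat)`, `affected`,
#'   `no-call` or `phasing-failure`.
#' @slot detail Table-style genotype string (e.g. `"Het, Mat"`, `"Hom"`).
#' @slot confidence Fraction of concordant informative votes.
#' @slot flags Character vector of warning flags.
#' @export
setClass("LinkageCall",
  representation(embryoId = "character", perParent = "list",
                 status = "character", detail = "character",
                 confidence = "numeric", flags = "character"))

#' EmbryoReport: integrated PGT report for one embryo
#'
#' @slot embryoId Embryo identifier.
#' @slot linkage A [LinkageCall-class] (status forced to phasing-failure when
#'   the ploidy screen is abnormal).
#' @slot cnv A [CNVResult-class].
#' @slot ploidy A [PloidyReport-class].
#' @slot roh A [ROHResult-class].
#' @slot flags Overall flags (`phasing-failure`, `low-confidence`).
#' @slot provenance list: seeds, config hash, package version.
#' @export
setClass("EmbryoReport",
  representation(embryoId = "character", linkage = "ANY", cnv = "CNVResult",
                 ploidy = "PloidyReport", roh = "ROHResult",
                 flags = "character", provenance = "list"))
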