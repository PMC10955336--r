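# The integrated per-embryo report: PGT-M linkage call plus the three PGT-A
# channels, with the cross-checks applied (an abnormal ploidy screen forces
# the linkage result to phasing-failure; ROH calls are filtered against
# copy-number segments).

#' Compile the integrated PGT report for one embryo
#'
#' @param embryoId Embryo identifier (must match the component results).
#' @param linkage A [LinkageCall-class].
#' @param cnv A [CNVResult-class]; its segment list must tile the genome
#'   (an empty list is a contract error).
#' @param ploidy A [PloidyReport-class].
#' @param roh An [ROHResult-class]; calls overlapping non-normal CNV
#'   segments are removed.
#' @param provenance list of seeds / config hash / versions to embed.
#' @return An [EmbryoReport-class].
#' @export
compileEmbryoReport <- function(embryoId, linkage, cnv, ploidy, roh,
                                provenance = list()) {
  if (nrow(cnvSegments(cnv)) == 0L)
    stopf("CNV stage must emit a whole-genome segment tiling; got none")
  if (!identical(linkage@embryoId, embryoId))
    stopf("embryo id mismatch: report '%s' vs linkage '%s'",
          embryoId, linkage@embryoId)
  flags <- character(0)
  if (ploidyCall(ploidy) != "normal") {
    linkage <- new("LinkageCall", embryoId = embryoId, perParent = list(),
                   status = "phasing-failure", detail = "-",
                   confidence = NA_real_, flags = "phasing-failure")
    flags <- c(flags, "phasing-failure")
  }
  if (!is.na(linkage@confidence) && linkage@confidence < 1)
    flags <- c(flags, "low-confidence")
  # re-apply the CNV exclusion in case ROH was called without segments
  seg <- cnvSegments(cnv)
  abn <- seg[seg$state != "normal", , drop = FALSE]
  win <- rohWindows(roh)
  if (nrow(abn) && nrow(rohRegions(roh))) {
    roh <- rohCalls(
      data.frame(chrom = win$chrom, start = win$start, end = win$end,
                 F = win$F1, callable = ifelse(win$callable, 40L, 0L)),
      win$F2, cnvSegments = seg)
    # keep the original per-window statistics; only the exclusion changed
    roh@windows$F1 <- win$F1
    roh@windows$logRatio <- win$logRatio
  }
  prov <- utils::modifyList(
    list(package = "phaselink",
         version = as.character(utils::packageVersion("phaselink"))),
    provenance)
  new("EmbryoReport", embryoId = embryoId, linkage = linkage, cnv = cnv,
      ploidy = ploidy, roh = roh, flags = flags, provenance = prov)
}

# plain-list view of a report, the JSON schema
reportToList <- function(report) {
  lk <- report@linkage
  perParent <- lapply(lk@perParent, function(p) list(
    votesRisk = p$votesRisk, votesNonrisk = p$votesNonrisk,
    label = p$label, confidence = p$confidence,
    mendelErrors = p$mendelErrors, crossovers = p$crossovers,
    origin = if (!is.null(p$votes)) p$votes[, c("pos", "vote")] else NULL))
  list(
    embryo = report@embryoId,
    pgtm = list(status = lk@status, detail = lk@detail,
                confidence = lk@confidence, flags = lk@flags,
                perParent = perParent),
    cnv = list(iscn = as.list(iscnStrings(report@cnv)),
               segments = cnvSegments(report@cnv)),
    ploidy = list(call = ploidyCall(report@ploidy),
                  karyotype = report@ploidy@karyotype,
                  threshold = report@ploidy@threshold,
                  chromosomes = chromosomeStats(report@ploidy)),
    roh = list(regions = rohRegions(report@roh)),
    flags = as.list(report@flags),
    provenance = report@provenance)
}

#' Write / read an embryo report as JSON
#'
#' The JSON is the canonical serialization: reading and re-writing it is
#' byte-stable.
#'
#' @param report An [EmbryoReport-class] (or the list read back).
#' @param path File path.
#' @return `path` / the report list.
#' @export
writeEmbryoReport <- function(report, path) {
  x <- if (is(report, "EmbryoReport")) reportToList(report) else report
  writeJson(x, path)
}

#' @rdname writeEmbryoReport
#' @export
readEmbryoReport <- function(path) {
  # no vector simplification: scalars, arrays and row-objects keep their
  # JSON shapes, so read -> write is byte-stable
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Cohort summary table across embryos
#'
#' One row per embryo, shaped like a clinical PGT results table: the
#' pathogenic-variation column and the CNV column side by side.
#'
#' @param reports List of [EmbryoReport-class] objects.
#' @return data.frame `embryo`, `pgtm`, `pgtmStatus`, `cnv`, `ploidy`,
#'   `rohRegions`.
#' @export
cohortTable <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    karyo <- if (ploidyCall(r@ploidy) %in% c("triploid-suspect",
                                             "haploid-suspect"))
      r@ploidy@karyotype else paste(iscnStrings(r@cnv), collapse = "; ")
    data.frame(embryo = r@embryoId,
               pgtm = r@linkage@detail,
               pgtmStatus = r@linkage@status,
               cnv = karyo,
               ploidy = ploidyCall(r@ploidy),
               rohRegions = nrow(rohRegions(r@roh)),
               stringsAsFactors = FALSE)
  }))
}

#' Write the cohort table as TSV
#'
#' @param reports List of [EmbryoReport-class] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCohortTsv <- function(reports, path) {
  utils::write.table(cohortTable(reports), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
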