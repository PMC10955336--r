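# Readers and writers for the pipeline's on-disk formats: a narrow
# biallelic VCF 4.2 dialect (phased parental truth, embryo genotype
# tables), the fragment TSV, window-count TSV, BED intervals and JSON
# reports. Parsing of VCF bodies goes through vcfR after a light structural
# pre-scan that reports malformed lines by line number.

vcfHeader <- function(map, formats, infos = character(0)) {
  reg <- mapRegions(map)
  c("##fileformat=VCFv4.2",
    "##source=phaselink",
    sprintf("##contig=<ID=%s,length=%d>", reg$chrom, reg$end),
    sprintf("##phaselinkRegion=%s:%d-%d", reg$chrom, reg$start, reg$end),
    infos, formats)
}

# structural pre-scan: consistent tab-field counts, numeric POS
validateVcfLines <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "##fileformat"))
    stopf("%s: line 1: missing ##fileformat header", basename(path))
  hdr <- which(startsWith(lines, "#CHROM"))
  if (length(hdr) != 1L)
    stopf("%s: missing #CHROM column header", basename(path))
  nCols <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1]])
  body <- setdiff(seq_along(lines), c(which(startsWith(lines, "##")), hdr))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != nCols)
      stopf("%s: line %d: expected %d tab-separated fields, found %d",
            basename(path), i, nCols, length(f))
    if (is.na(suppressWarnings(as.numeric(f[2]))))
      stopf("%s: line %d: POS '%s' is not numeric", basename(path), i, f[2])
    if (grepl(",", f[5], fixed = TRUE))
      stopf("%s: line %d: multi-allelic ALT '%s' is not supported",
            basename(path), i, f[5])
  }
  invisible(lines)
}

regionsFromHeader <- function(lines) {
  rl <- grep("^##phaselinkRegion=", lines, value = TRUE)
  if (!length(rl)) return(NULL)
  m <- regmatches(rl, regexec("^##phaselinkRegion=([^:]+):([0-9]+)-([0-9]+)$", rl))
  do.call(rbind, lapply(m, function(x)
    data.frame(chrom = x[2], start = as.numeric(x[3]), end = as.numeric(x[4]),
               stringsAsFactors = FALSE)))
}

#' Write phased parental truth as a VCF
#'
#' GT is phased (`hap1|hap2`) for both parents; target sites carry the
#' `TARGET` INFO flag and markers their simulated `MAF`.
#'
#' @param truth A [ParentalTruth-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeParentalVcf <- function(truth, path) {
  map <- truthMap(truth)
  s <- markerSites(map)
  haps <- truthHaplotypes(truth)
  info <- sprintf("MAF=%.4f", s$maf)
  ct <- carrierTable(map)
  tg <- targetSpec(map)
  for (i in targetIndices(map)) {
    who <- sort(ct$parent[ct$site == i])
    info[i] <- sprintf("TARGET;CARRIER=%s;INHERITANCE=%s",
                       paste(who, collapse = ","),
                       if (is.null(tg)) "AD" else tg@inheritance)
  }
  gt <- function(h) paste0(h[1, ], "|", h[2, ])
  hdr <- vcfHeader(map,
    formats = "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    infos = c("##INFO=<ID=TARGET,Number=0,Type=Flag,Description=\"Pathogenic target site\">",
              "##INFO=<ID=CARRIER,Number=.,Type=String,Description=\"Carrier parent(s) of the target\">",
              "##INFO=<ID=INHERITANCE,Number=1,Type=String,Description=\"Inheritance mode\">",
              "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Simulated minor allele frequency\">"))
  body <- paste(s$chrom, format(s$pos, scientific = FALSE, trim = TRUE), ".",
                s$ref, s$alt, ".", "PASS", info, "GT",
                gt(haps$maternal), gt(haps$paternal), sep = "\t")
  writeLines(c(hdr,
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "MOTHER", "FATHER", sep = "\t"),
               body), path)
  invisible(path)
}

#' Read a phased parental VCF
#'
#' @param path A VCF written by [writeParentalVcf()] (or the same dialect:
#'   biallelic, phased GT for samples MOTHER and FATHER).
#' @return list `map` ([MarkerMap-class]), `haplotypes`, `genotypes` (as in
#'   [ParentalTruth-class]).
#' @export
readParentalVcf <- function(path) {
  lines <- validateVcfLines(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  info <- fix[, "INFO"]
  maf <- suppressWarnings(as.numeric(sub("^MAF=", "", info)))
  role <- ifelse(grepl("TARGET", info, fixed = TRUE), "target", "marker")
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  varType <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV",
                    ifelse(nchar(ref) > nchar(alt), "DEL", "INS"))
  sites <- data.frame(chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
                      ref = ref, alt = alt, var_type = varType, role = role,
                      maf = maf, stringsAsFactors = FALSE)
  regions <- regionsFromHeader(lines)
  if (is.null(regions))
    regions <- do.call(rbind, lapply(unique(sites$chrom), function(ch)
      data.frame(chrom = ch, start = min(sites$pos[sites$chrom == ch]),
                 end = max(sites$pos[sites$chrom == ch]))))
  target <- NULL
  tIdx <- which(role == "target")
  if (length(tIdx)) {
    getField <- function(i, key) {
      m <- regmatches(info[i], regexec(paste0(key, "=([^;]+)"), info[i]))[[1]]
      if (length(m) == 2L) m[2] else NA_character_
    }
    carriers <- lapply(tIdx, function(i)
      strsplit(getField(i, "CARRIER"), ",", fixed = TRUE)[[1]])
    inh <- getField(tIdx[1], "INHERITANCE")
    if (is.na(inh)) inh <- "AD"
    primary <- tIdx[vapply(carriers, function(x) "maternal" %in% x, logical(1))]
    primary <- if (length(primary)) primary[1] else tIdx[1]
    priParent <- if ("maternal" %in% carriers[[match(primary, tIdx)]])
      "maternal" else "paternal"
    partner <- NULL
    if (length(tIdx) > 1L) {
      o <- setdiff(tIdx, primary)[1]
      partner <- sites[o, c("chrom", "pos", "ref", "alt", "var_type")]
    } else if (length(carriers[[1]]) == 2L) {
      partner <- sites[primary, c("chrom", "pos", "ref", "alt", "var_type")]
    }
    target <- pathogenicTarget(sites$chrom[primary], sites$pos[primary],
                               sites$ref[primary], sites$alt[primary],
                               varType = sites$var_type[primary],
                               parent = priParent, inheritance = inh,
                               partner = partner)
  }
  map <- new("MarkerMap", regions = regions, sites = sites, target = target)
  gtm <- v@gt[, c("MOTHER", "FATHER"), drop = FALSE]
  parseHaps <- function(col) {
    al <- gtAlleles(col)
    rbind(al[1, ], al[2, ])
  }
  haps <- list(maternal = parseHaps(gtm[, "MOTHER"]),
               paternal = parseHaps(gtm[, "FATHER"]))
  geno <- lapply(haps, function(h)
    paste(pmin(h[1, ], h[2, ]), pmax(h[1, ], h[2, ]), sep = "/"))
  list(map = map, haplotypes = haps, genotypes = geno)
}

#' Write embryo genotype calls as a VCF
#'
#' @param embryo An [EmbryoGenotypes-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeEmbryoVcf <- function(embryo, path) {
  map <- embryo@map
  s <- markerSites(map)
  calls <- genotypeCalls(embryo)
  hdr <- vcfHeader(map, formats = c(
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths (ref,alt)\">"))
  sample <- sprintf("%s:%d:%d,%d", calls$gt, calls$dp,
                    calls$dp - calls$altDp, calls$altDp)
  body <- paste(s$chrom, format(s$pos, scientific = FALSE, trim = TRUE), ".",
                s$ref, s$alt, ".", "PASS", ".", "GT:DP:AD", sample, sep = "\t")
  writeLines(c(hdr,
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", embryoId(embryo), sep = "\t"),
               body), path)
  invisible(path)
}

#' Read an embryo genotype VCF
#'
#' @param path VCF path (GT:DP:AD dialect from [writeEmbryoVcf()]).
#' @param map Optional [MarkerMap-class] to index sites against; when NULL
#'   a minimal map is rebuilt from the records.
#' @return An [EmbryoGenotypes-class].
#' @export
readEmbryoVcf <- function(path, map = NULL) {
  lines <- validateVcfLines(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  sampleName <- colnames(v@gt)[2]
  parts <- strsplit(v@gt[, 2], ":", fixed = TRUE)
  gt <- vapply(parts, `[`, character(1), 1L)
  dp <- as.integer(vapply(parts, `[`, character(1), 2L))
  ad <- vapply(parts, `[`, character(1), 3L)
  altDp <- as.integer(vapply(strsplit(ad, ",", fixed = TRUE), `[`, character(1), 2L))
  chrom <- fix[, "CHROM"]; pos <- as.numeric(fix[, "POS"])
  if (is.null(map)) {
    ref <- fix[, "REF"]; alt <- fix[, "ALT"]
    varType <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV",
                      ifelse(nchar(ref) > nchar(alt), "DEL", "INS"))
    regions <- regionsFromHeader(lines)
    if (is.null(regions))
      regions <- do.call(rbind, lapply(unique(chrom), function(ch)
        data.frame(chrom = ch, start = min(pos[chrom == ch]),
                   end = max(pos[chrom == ch]))))
    map <- new("MarkerMap", regions = regions,
               sites = data.frame(chrom = chrom, pos = pos, ref = ref,
                                  alt = alt, var_type = varType,
                                  role = "marker", maf = NA_real_,
                                  stringsAsFactors = FALSE),
               target = NULL)
  }
  s <- markerSites(map)
  site <- match(paste(chrom, pos), paste(s$chrom, s$pos))
  if (anyNA(site)) stopf("embryo VCF contains sites absent from the marker map")
  calls <- data.frame(site = site, chrom = chrom, pos = pos, gt = gt,
                      dp = dp, altDp = altDp,
                      baf = ifelse(dp > 0, altDp / dp, NA_real_),
                      stringsAsFactors = FALSE)
  new("EmbryoGenotypes", embryoId = sampleName, map = map, calls = calls)
}

#' Write barcoded fragments as TSV
#'
#' One row per fragment: `barcode`, `chrom`, `start`, `end` (0-based
#' half-open) and `observations` as semicolon-joined
#' `siteIndex:alleleCode:quality` triples.
#'
#' @param fragments A [FragmentSet-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFragmentsTsv <- function(fragments, path) {
  fr <- fragmentTable(fragments)
  ob <- fragmentObservations(fragments)
  obsStr <- rep("", nrow(fr))
  if (nrow(ob)) {
    sp <- split(sprintf("%d:%d:%g", ob$site, ob$allele, ob$qual), ob$fragment)
    obsStr[as.integer(names(sp))] <- vapply(sp, paste, character(1),
                                            collapse = ";")
  }
  df <- data.frame(barcode = fr$barcode, chrom = fr$chrom,
                   start = fr$start, end = fr$end, observations = obsStr,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fragment TSV
#'
#' @param path Path written by [writeFragmentsTsv()].
#' @param nSites Number of sites in the accompanying marker map.
#' @param parent Parent label to attach.
#' @return A [FragmentSet-class].
#' @export
readFragmentsTsv <- function(path, nSites, parent = "maternal") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric",
                                         "numeric", "character"))
  obs <- lapply(seq_len(nrow(df)), function(i) {
    if (!nzchar(df$observations[i])) return(NULL)
    triples <- strsplit(strsplit(df$observations[i], ";", fixed = TRUE)[[1]],
                        ":", fixed = TRUE)
    data.frame(fragment = i,
               site = as.integer(vapply(triples, `[`, character(1), 1L)),
               allele = as.integer(vapply(triples, `[`, character(1), 2L)),
               qual = as.numeric(vapply(triples, `[`, character(1), 3L)))
  })
  obs <- do.call(rbind, obs)
  if (is.null(obs))
    obs <- data.frame(fragment = integer(0), site = integer(0),
                      allele = integer(0), qual = numeric(0))
  new("FragmentSet", parent = parent,
      fragments = data.frame(barcode = df$barcode, chrom = df$chrom,
                             start = df$start, end = df$end,
                             hap = NA_integer_, stringsAsFactors = FALSE),
      observations = obs, nSites = as.integer(nSites))
}

#' Write / read a window-count track as TSV
#'
#' Columns: `chrom`, `start`, `end` (0-based half-open), `test`, then one
#' column per reference sample.
#'
#' @param track A [WindowCountTrack-class].
#' @param path File path.
#' @return `path` / a [WindowCountTrack-class].
#' @export
writeWindowCountsTsv <- function(track, path) {
  df <- cbind(track@windows, test = track@test, as.data.frame(track@reference))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeWindowCountsTsv
#' @export
readWindowCountsTsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  refCols <- setdiff(names(df), c("chrom", "start", "end", "test"))
  new("WindowCountTrack",
      windows = df[, c("chrom", "start", "end")],
      test = as.numeric(df$test),
      reference = as.matrix(df[, refCols, drop = FALSE]),
      log2rr = rep(NA_real_, nrow(df)), masked = rep(FALSE, nrow(df)))
}

#' Write copy-number segments as BED
#'
#' BED columns: chrom, start, end (0-based half-open), name = state,
#' score = round(100 * mosaic fraction).
#'
#' @param cnv A [CNVResult-class] or its segment data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSegmentsBed <- function(cnv, path) {
  seg <- if (is(cnv, "CNVResult")) cnvSegments(cnv) else cnv
  df <- data.frame(seg$chrom, format(seg$start, scientific = FALSE, trim = TRUE),
                   format(seg$end, scientific = FALSE, trim = TRUE),
                   seg$state, round(100 * seg$mosaicFraction))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write ROH regions as BED
#'
#' @param roh An [ROHResult-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeRohBed <- function(roh, path) {
  r <- rohRegions(roh)
  if (nrow(r) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  df <- data.frame(r$chrom, format(r$start, scientific = FALSE, trim = TRUE),
                   format(r$end, scientific = FALSE, trim = TRUE),
                   "ROH", round(-100 * pmax(pmin(r$meanLogRatio, 0), -3) / 3))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# canonical JSON emitter used by every report writer (stable key order,
# no rounding surprises)
writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Serialize a signed haplotype pair to JSON
#'
#' @param signed A [SignedHaplotypePair-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSignedJson <- function(signed, path) {
  writeJson(list(
    parent = signed@parent, call = signed@call, riskHap = signed@riskHap,
    consistency = signed@consistency, spanningReads = signed@spanningReads,
    targetSite = signed@targetSite, targetPos = signed@targetPos,
    spanUp = signed@spanUp, spanDown = signed@spanDown,
    blocks = phasedSites(signed), informative = informativeSnps(signed)), path)
}

#' Read a signed haplotype pair from JSON
#'
#' @param path Path written by [writeSignedJson()].
#' @return A [SignedHaplotypePair-class].
#' @export
readSignedJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  blocks <- as.data.frame(x$blocks)
  info <- as.data.frame(x$informative)
  if (!nrow(info))
    info <- data.frame(site = integer(0), pos = numeric(0),
                       side = character(0), distance = numeric(0),
                       riskAllele = integer(0), otherGt = character(0))
  new("SignedHaplotypePair", parent = x$parent,
      phased = new("PhasedHaplotypes", sites = blocks,
                   nFragments = NA_integer_),
      targetSite = as.integer(x$targetSite), targetPos = x$targetPos,
      call = x$call, riskHap = if (is.null(x$riskHap)) NA_character_ else x$riskHap,
      consistency = if (is.null(x$consistency)) NA_real_ else x$consistency,
      spanningReads = as.integer(x$spanningReads),
      spanUp = x$spanUp, spanDown = x$spanDown, informative = info)
}
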