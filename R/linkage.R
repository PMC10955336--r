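# Embryo linkage analysis: resolve each informative SNP into the allele
# transmitted by the carrier parent, vote risk / non-risk against the signed
# haplotype, smooth the votes, detect crossovers, and call carrier status.

#' Resolve embryo genotypes into per-site origin votes
#'
#' At each informative SNP the embryo genotype, combined with the other
#' parent's homozygous genotype, deterministically yields the allele
#' transmitted by the focal (carrier) parent; the vote is `risk` or
#' `nonrisk` according to the signed haplotype. Missing genotypes abstain;
#' genotypes impossible given the parents (e.g. an allele neither parent
#' could transmit, the signature of allele dropout) abstain and increment
#' the Mendelian-error counter.
#'
#' @param embryo An [EmbryoGenotypes-class].
#' @param signed A signed [SignedHaplotypePair-class] with informative SNPs
#'   selected.
#' @return data.frame `site`, `pos`, `transmitted` (0/1/NA), `vote`
#'   (`risk`, `nonrisk`, `abstain-missing`, `mendel-error`).
#' @export
assignEmbryoAlleles <- function(embryo, signed) {
  info <- informativeSnps(signed)
  if (nrow(info) == 0L)
    stopf("no informative SNPs; run selectInformativeSnps() first")
  calls <- genotypeCalls(embryo)
  gt <- calls$gt[match(info$site, calls$site)]
  eal <- gtAlleles(gt)
  oal <- gtAlleles(info$otherGt)[1, ]  # other parent is homozygous
  transmitted <- rep(NA_integer_, nrow(info))
  vote <- character(nrow(info))
  for (k in seq_len(nrow(info))) {
    a <- eal[, k]
    if (anyNA(a)) { vote[k] <- "abstain-missing"; next }
    o <- oal[k]
    if (!o %in% a) { vote[k] <- "mendel-error"; next }
    # remove one copy of the other parent's obligate allele
    transmitted[k] <- if (a[1] == o) a[2] else a[1]
    vote[k] <- if (transmitted[k] == info$riskAllele[k]) "risk" else "nonrisk"
  }
  data.frame(site = info$site, pos = info$pos, transmitted = transmitted,
             vote = vote, stringsAsFactors = FALSE)
}

#' Smooth origin votes and detect crossovers
#'
#' Votes are smoothed by majority over runs: any run of identical labels
#' shorter than `minRun` is absorbed into its neighbours and flagged as
#' genotyping error, so a single discordant vote (one allele dropout) can
#' never create a crossover. A crossover is reported between two remaining
#' opposite-label runs, positioned midway between the flanking votes.
#'
#' @param votes Vote table from [assignEmbryoAlleles()] (abstentions are
#'   ignored).
#' @param minRun Minimum run length supporting a segment (default 3).
#' @return list with `segments` (data.frame `label`, `startPos`, `endPos`,
#'   `nVotes`), `crossovers` (numeric positions), `errorVotes` (positions of
#'   error-flagged votes), `smoothed` (the per-vote smoothed labels).
#' @export
smoothAndDetectCrossovers <- function(votes, minRun = 3L) {
  v <- votes[votes$vote %in% c("risk", "nonrisk"), , drop = FALSE]
  if (nrow(v) == 0L) stopf("no risk/nonrisk votes to smooth")
  v <- v[order(v$pos), , drop = FALSE]
  lab <- v$vote
  errPos <- numeric(0)
  # iteratively absorb the shortest sub-minimum run into its neighbours
  repeat {
    r <- rle(lab)
    if (length(r$lengths) == 1L) break
    short <- which(r$lengths < minRun)
    if (!length(short)) break
    k <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    idx <- (ends[k] - r$lengths[k] + 1L):ends[k]
    errPos <- c(errPos, v$pos[idx])
    newLab <- if (k == 1L) r$values[2L] else r$values[k - 1L]
    lab[idx] <- newLab
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segments <- data.frame(label = r$values,
                         startPos = v$pos[starts], endPos = v$pos[ends],
                         nVotes = r$lengths, stringsAsFactors = FALSE)
  crossovers <- if (nrow(segments) > 1L)
    (segments$endPos[-nrow(segments)] + segments$startPos[-1L]) / 2
  else numeric(0)
  list(segments = segments, crossovers = crossovers,
       errorVotes = sort(errPos), smoothed = lab)
}

#' Call the transmitted haplotype at the target position
#'
#' The transmitted label is the label of the smoothed segments flanking the
#' target: a call requires the nearest upstream and downstream segments to
#' agree, each backed by at least `minFlankVotes` concordant votes. A
#' crossover bracketing the target (flanks disagreeing) is a no-call - the
#' flanking-marker safeguard against misdiagnosis by recombination. A
#' one-sided call (the other flank empty or under-supported) is allowed but
#' flagged reduced-confidence.
#'
#' @param smoothed Result of [smoothAndDetectCrossovers()].
#' @param targetPos Target position (bp).
#' @param minFlankVotes Minimum concordant votes per flank (default 3).
#' @return list `label` (`"risk"`, `"nonrisk"` or `NA` for no-call),
#'   `flags` (character vector, may contain `"one-flank"`).
#' @export
callInheritance <- function(smoothed, targetPos, minFlankVotes = 3L) {
  seg <- smoothed$segments
  flankOf <- function(side) {
    cand <- if (side == "up") seg[seg$startPos < targetPos, , drop = FALSE]
            else seg[seg$endPos > targetPos, , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    cand[if (side == "up") nrow(cand) else 1L, , drop = FALSE]
  }
  up <- flankOf("up"); down <- flankOf("down")
  okUp <- !is.null(up) && up$nVotes >= minFlankVotes
  okDown <- !is.null(down) && down$nVotes >= minFlankVotes
  if (okUp && okDown) {
    if (up$label == down$label) return(list(label = up$label, flags = character(0)))
    return(list(label = NA_character_, flags = "crossover-at-target"))
  }
  if (okUp || okDown) {
    one <- if (okUp) up else down
    # the weak flank may still disagree - if it does, refuse
    weak <- if (okUp) down else up
    if (!is.null(weak) && weak$label != one$label)
      return(list(label = NA_character_, flags = "crossover-at-target"))
    return(list(label = one$label, flags = "one-flank"))
  }
  list(label = NA_character_, flags = "insufficient-votes")
}

#' Combine per-parent transmitted labels into carrier status
#'
#' Autosomal dominant: a risk label from the carrier parent is affected
#' (Het), non-risk is unaffected (WT). Autosomal recessive with the same
#' variant in both parents: risk from both is affected (Hom), exactly one is
#' a carrier annotated with the parent of origin, none is WT. Compound
#' heterozygous: risk from both parents is affected (compound het), one is a
#' carrier. Any no-call label makes the overall status no-call.
#'
#' @param labels Named list of transmitted labels per analysed carrier
#'   parent (`"maternal"`/`"paternal"` -> `"risk"`, `"nonrisk"` or `NA`).
#' @param target The [PathogenicTarget-class].
#' @return list `status` (`unaffected`, `carrier(mat)`, `carrier(pat)`,
#'   `affected`, `no-call`) and `detail` (report-style genotype string).
#' @export
callCarrierStatus <- function(labels, target) {
  if (any(vapply(labels, is.na, logical(1))))
    return(list(status = "no-call", detail = "-"))
  risk <- names(labels)[vapply(labels, identical, logical(1), "risk")]
  if (target@inheritance == "AD" || nrow(target@partnerSite) == 0L) {
    carrier <- target@parent
    if (carrier %in% risk)
      return(list(status = "affected",
                  detail = sprintf("Het, %s",
                                   if (carrier == "maternal") "Mat" else "Pat")))
    return(list(status = "unaffected", detail = "WT"))
  }
  # AR with a pathogenic allele on each parent
  compound <- !sameVariant(target)
  if (length(risk) == 2L)
    return(list(status = "affected",
                detail = if (compound) "compound Het" else "Hom"))
  if (length(risk) == 1L) {
    who <- if (risk == "maternal") "mat" else "pat"
    return(list(status = sprintf("carrier(%s)", who),
                detail = sprintf("Het, %s", if (risk == "maternal") "Mat" else "Pat")))
  }
  list(status = "unaffected", detail = "WT")
}

#' Run the full linkage analysis for one embryo
#'
#' @param embryo An [EmbryoGenotypes-class].
#' @param signedList Named list of signed [SignedHaplotypePair-class]
#'   objects (informative SNPs selected), one per carrier parent.
#' @param target The [PathogenicTarget-class].
#' @param ploidyAbnormal Logical; when TRUE (e.g. the Z-score screen flags a
#'   triploid) the analysis refuses with status `phasing-failure` and
#'   reports no genotype.
#' @param minRun,minFlankVotes Smoothing/calling parameters.
#' @param maxMendelRate Maximum tolerated fraction of Mendelian-inconsistent
#'   informative sites before a whole-embryo no-call (default 0.10; guards
#'   against contamination).
#' @return A [LinkageCall-class].
#' @export
runLinkage <- function(embryo, signedList, target, ploidyAbnormal = FALSE,
                       minRun = 3L, minFlankVotes = 3L, maxMendelRate = 0.10) {
  if (isTRUE(ploidyAbnormal))
    return(new("LinkageCall", embryoId = embryoId(embryo),
               perParent = list(), status = "phasing-failure", detail = "-",
               confidence = NA_real_, flags = "phasing-failure"))
  labels <- list()
  perParent <- list()
  flags <- character(0)
  confs <- numeric(0)
  for (parent in names(signedList)) {
    signed <- signedList[[parent]]
    if (signingCall(signed) != "signed") {
      labels[[parent]] <- NA_character_
      flags <- c(flags, sprintf("%s-unsigned", parent))
      next
    }
    votes <- assignEmbryoAlleles(embryo, signed)
    cast <- votes$vote %in% c("risk", "nonrisk")
    mendel <- sum(votes$vote == "mendel-error")
    mendelRate <- mendel / nrow(votes)
    if (mendelRate > maxMendelRate) {
      labels[[parent]] <- NA_character_
      flags <- c(flags, sprintf("%s-mendel-excess", parent))
      perParent[[parent]] <- list(votes = votes, mendelErrors = mendel,
                                  label = NA_character_)
      next
    }
    if (!any(cast)) {
      labels[[parent]] <- NA_character_
      flags <- c(flags, sprintf("%s-no-votes", parent))
      next
    }
    sm <- smoothAndDetectCrossovers(votes, minRun = minRun)
    call <- callInheritance(sm, signed@targetPos, minFlankVotes = minFlankVotes)
    labels[[parent]] <- call$label
    if (length(call$flags))
      flags <- c(flags, sprintf("%s-%s", parent, call$flags))
    conf <- if (!is.na(call$label))
      mean(votes$vote[cast] == call$label) else NA_real_
    confs <- c(confs, conf)
    perParent[[parent]] <- list(
      votes = votes,
      votesRisk = sum(votes$vote == "risk"),
      votesNonrisk = sum(votes$vote == "nonrisk"),
      crossovers = sm$crossovers, errorVotes = sm$errorVotes,
      label = call$label, confidence = conf, mendelErrors = mendel)
  }
  st <- callCarrierStatus(labels, target)
  new("LinkageCall", embryoId = embryoId(embryo), perParent = perParent,
      status = st$status, detail = st$detail,
      confidence = if (length(confs)) min(confs, na.rm = FALSE) else NA_real_,
      flags = flags)
}
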