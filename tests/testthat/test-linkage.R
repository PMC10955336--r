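# Embryo linkage: vote deduction, smoothing, crossover detection, carrier
# status and the abnormal-ploidy refusal.

# a signed pair + embryo genotype table built by hand: 20 informative SNPs
# at 100 kb spacing, target at 1.05e6, risk allele = 1 everywhere
handLinkageFixture <- function(votePattern, otherAllele = 0L) {
  n <- length(votePattern)
  pos <- seq(1e5, by = 1e5, length.out = n)
  targetPos <- max(pos) + 5e4  # markers upstream, target after them
  info <- data.frame(site = seq_len(n), pos = pos,
                     side = ifelse(pos < targetPos, "upstream", "downstream"),
                     distance = abs(pos - targetPos), riskAllele = 1L,
                     otherGt = sprintf("%d/%d", otherAllele, otherAllele),
                     stringsAsFactors = FALSE)
  signed <- new("SignedHaplotypePair", parent = "maternal",
                phased = new("PhasedHaplotypes",
                             sites = data.frame(site = seq_len(n), block = 1L,
                                                hapA = 1L, conf = 1),
                             nFragments = 0L),
                targetSite = n + 1L, targetPos = targetPos, call = "signed",
                riskHap = "A", consistency = 1, spanningReads = 10L,
                spanUp = 2e6, spanDown = 2e6, informative = info)
  # votePattern: "r" risk, "n" nonrisk, "." missing, "x" mendel-error
  gt <- vapply(votePattern, function(v) switch(v,
    r = sprintf("%d/1", otherAllele), n = sprintf("%d/0", otherAllele),
    "." = "./.", x = "9/9"), character(1))
  gt[gt == "0/0"] <- "0/0"; gt <- sub("0/1", "0/1", gt)
  gt <- vapply(seq_along(gt), function(i) {
    a <- suppressWarnings(sort(as.integer(strsplit(gt[i], "/")[[1]])))
    if (length(a) < 2 || anyNA(a)) if (gt[i] == "9/9") "9/9" else "./."
    else paste(a, collapse = "/")
  }, character(1))
  map <- new("MarkerMap",
             regions = data.frame(chrom = "chr1", start = 1, end = 3e6),
             sites = data.frame(chrom = "chr1", pos = c(pos, targetPos),
                                ref = "A", alt = "T", var_type = "SNV",
                                role = c(rep("marker", n), "target"),
                                maf = c(rep(0.3, n), NA)),
             target = pathogenicTarget("chr1", targetPos, "A", "T"))
  embryo <- new("EmbryoGenotypes", embryoId = "E1", map = map,
                calls = data.frame(site = seq_len(n + 1), chrom = "chr1",
                                   pos = c(pos, targetPos),
                                   gt = c(gt, "./."), dp = 30L, altDp = 15L,
                                   baf = 0.5, stringsAsFactors = FALSE))
  list(signed = signed, embryo = embryo,
       target = pathogenicTarget("chr1", targetPos, "A", "T"))
}

test_that("embryo genotypes resolve into transmitted-allele votes", {
  fx <- handLinkageFixture(c("r", "n", ".", "x", "r"))
  votes <- assignEmbryoAlleles(fx$embryo, fx$signed)
  expect_equal(votes$vote,
               c("risk", "nonrisk", "abstain-missing", "mendel-error", "risk"))
  expect_equal(votes$transmitted, c(1L, 0L, NA, NA, 1L))
})

test_that("an embryo genotype missing the other parent's obligate allele abstains as a Mendelian error", {
  # the other parent is 0/0, so the embryo must carry one 0; a 1/1 call
  # (the signature of allele dropout) cannot be resolved and must abstain
  fx <- handLinkageFixture(rep("r", 3))
  calls <- genotypeCalls(fx$embryo)
  calls$gt[2] <- "1/1"
  fx$embryo@calls <- calls
  votes <- assignEmbryoAlleles(fx$embryo, fx$signed)
  expect_equal(votes$vote[2], "mendel-error")
  expect_true(is.na(votes$transmitted[2]))
})

test_that("vote smoothing suppresses singletons and finds real crossovers", {
  mkVotes <- function(pattern) data.frame(
    site = seq_along(pattern), pos = seq_along(pattern) * 1e5,
    transmitted = 1L,
    vote = ifelse(pattern == "r", "risk", "nonrisk"))
  allRisk <- smoothAndDetectCrossovers(mkVotes(rep("r", 10)))
  expect_equal(nrow(allRisk$segments), 1L)
  expect_length(allRisk$crossovers, 0L)

  co <- smoothAndDetectCrossovers(mkVotes(c(rep("r", 20), rep("n", 20))))
  expect_length(co$crossovers, 1L)
  expect_equal(co$crossovers, (20 * 1e5 + 21 * 1e5) / 2)

  single <- smoothAndDetectCrossovers(
    mkVotes(c(rep("r", 8), "n", rep("r", 8))))
  expect_length(single$crossovers, 0L)
  expect_equal(single$errorVotes, 9e5)
})

test_that("inheritance is called from the flanks with the crossover safeguard", {
  seg <- function(labels, starts, ends, n) list(segments = data.frame(
    label = labels, startPos = starts, endPos = ends, nVotes = n))
  both <- callInheritance(seg("risk", 1e5, 2e6, 20L), targetPos = 1e6)
  expect_equal(both$label, "risk")
  expect_length(both$flags, 0L)

  disagree <- callInheritance(
    seg(c("risk", "nonrisk"), c(1e5, 1.1e6), c(9e5, 2e6), c(10L, 10L)),
    targetPos = 1e6)
  expect_true(is.na(disagree$label))
  expect_equal(disagree$flags, "crossover-at-target")

  oneFlank <- callInheritance(
    seg("nonrisk", 1.1e6, 2e6, 10L), targetPos = 1e6)
  expect_equal(oneFlank$label, "nonrisk")
  expect_equal(oneFlank$flags, "one-flank")

  starved <- callInheritance(
    seg(c("risk", "risk"), c(1e5, 1.1e6), c(9e5, 2e6), c(2L, 2L)),
    targetPos = 1e6)
  expect_true(is.na(starved$label))
})

test_that("carrier status combines parental labels per inheritance mode", {
  ad <- pathogenicTarget("chr1", 1e6, "A", "T", parent = "maternal",
                         inheritance = "AD")
  expect_equal(callCarrierStatus(list(maternal = "risk"), ad),
               list(status = "affected", detail = "Het, Mat"))
  expect_equal(callCarrierStatus(list(maternal = "nonrisk"), ad),
               list(status = "unaffected", detail = "WT"))
  ar <- pathogenicTarget("chr1", 1e6, "A", "T", parent = "maternal",
                         inheritance = "AR",
                         partner = data.frame(chrom = "chr1", pos = 1e6,
                                              ref = "A", alt = "T"))
  expect_equal(callCarrierStatus(list(maternal = "risk", paternal = "risk"),
                                 ar)$detail, "Hom")
  expect_equal(callCarrierStatus(list(maternal = "risk",
                                      paternal = "nonrisk"), ar)$status,
               "carrier(mat)")
  expect_equal(callCarrierStatus(list(maternal = "nonrisk",
                                      paternal = "nonrisk"), ar)$detail, "WT")
  ch <- pathogenicTarget("chr11", 5247993, "AC", "A", varType = "DEL",
                         parent = "maternal", inheritance = "AR",
                         partner = data.frame(chrom = "chr11", pos = 5248200,
                                              ref = "A", alt = "T"))
  expect_equal(callCarrierStatus(list(maternal = "risk", paternal = "risk"),
                                 ch)$detail, "compound Het")
  expect_equal(callCarrierStatus(list(maternal = NA_character_,
                                      paternal = "risk"), ch)$status,
               "no-call")
})

test_that("relabelling risk and non-risk flips every call but not the crossovers", {
  fx <- familyFixture()
  et <- simulateEmbryo(fx$truth, crossovers = list(maternal = 1.2e6),
                       transmit = list(maternal = "nonrisk"), seed = 61)
  eg <- simulateEmbryoGenotypes(et, fx$truth, embryoId = "S1", seed = 62)
  lk1 <- runLinkage(eg, list(maternal = fx$signed), fx$target)
  flipped <- fx$signed
  flipped@riskHap <- if (flipped@riskHap == "A") "B" else "A"
  flipped@informative$riskAllele <- 1L - flipped@informative$riskAllele
  lk2 <- runLinkage(eg, list(maternal = flipped), fx$target)
  l1 <- lk1@perParent$maternal$label
  l2 <- lk2@perParent$maternal$label
  expect_false(identical(l1, l2))
  expect_setequal(c(l1, l2), c("risk", "nonrisk"))
  expect_equal(lk1@perParent$maternal$crossovers,
               lk2@perParent$maternal$crossovers)
})

test_that("an abnormal ploidy screen forces phasing-failure with no genotype", {
  fx <- familyFixture()
  et <- simulateEmbryo(fx$truth, ploidy = "triploid", seed = 71)
  eg <- simulateEmbryoGenotypes(et, fx$truth, embryoId = "T1", seed = 72)
  lk <- runLinkage(eg, list(maternal = fx$signed), fx$target,
                   ploidyAbnormal = TRUE)
  expect_equal(linkageStatus(lk), "phasing-failure")
  expect_equal(lk@detail, "-")
  expect_length(lk@perParent, 0L)
})

test_that("carrier status is recovered across simulated embryos and wrong calls are never confident", {
  fx <- familyFixture()
  nOK <- 0L; nCall <- 0L
  for (k in 1:30) {
    et <- simulateEmbryo(fx$truth,
                         transmit = list(maternal = if (k %% 2) "risk"
                                                    else "nonrisk"),
                         seed = 500 + k)
    eg <- simulateEmbryoGenotypes(et, fx$truth, adoRate = 0.10,
                                  perReadError = 0.01,
                                  embryoId = sprintf("L%d", k),
                                  seed = 600 + k)
    lk <- runLinkage(eg, list(maternal = fx$signed), fx$target)
    hap <- truthHaplotypes(fx$truth)$maternal
    truthAffected <- hap[et@transmitted$maternal[fx$tIdx], fx$tIdx] == 1L
    want <- if (truthAffected) "affected" else "unaffected"
    if (linkageStatus(lk) != "no-call") {
      nCall <- nCall + 1L
      if (linkageStatus(lk) == want) nOK <- nOK + 1L
      else expect_lt(lk@confidence, 1)
    }
  }
  expect_gte(nCall, 25L)
  expect_gte(nOK / nCall, 0.99)
})
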