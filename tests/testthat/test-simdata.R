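# The synthetic-data engine: seeded determinism, the statistical structure
# the analyses assume, and its error models.

test_that("marker maps are seeded, sorted and hold the target at its position", {
  tg <- pathogenicTarget("chr11", 5248200, "A", "T", parent = "paternal",
                         inheritance = "AR")
  m1 <- buildMarkerMap("chr11", 3248200, 7248200, nMarkers = 400,
                       target = tg, seed = 7)
  m2 <- buildMarkerMap("chr11", 3248200, 7248200, nMarkers = 400,
                       target = tg, seed = 7)
  expect_identical(markerSites(m1), markerSites(m2))
  s <- markerSites(m1)
  expect_equal(nrow(s), 401L)
  expect_equal(sum(s$role == "target"), 1L)
  expect_equal(s$pos[s$role == "target"], 5248200)
  expect_false(is.unsorted(s$pos, strictly = TRUE))
  m3 <- buildMarkerMap("chr11", 3248200, 7248200, nMarkers = 400,
                       target = tg, seed = 8)
  expect_false(identical(markerSites(m1)$pos, markerSites(m3)$pos))
})

test_that("a region too small for distinct positions is an explicit error", {
  expect_error(buildMarkerMap("chr1", 100, 109, nMarkers = 11, seed = 1),
               "cannot hold")
  expect_error(buildMarkerMap("chr1", 100, 100, nMarkers = 2, seed = 1),
               "empty region")
})

test_that("parental truth places the pathogenic allele on exactly one carrier haplotype", {
  fx <- familyFixture()
  haps <- truthHaplotypes(fx$truth)
  tIdx <- fx$tIdx
  expect_equal(sum(haps$maternal[, tIdx]), 1L)   # AD maternal carrier
  expect_equal(sum(haps$paternal[, tIdx]), 0L)   # non-carrier is 0|0
  # same seed, same truth
  tr2 <- makeParentalTruth(fx$map, seed = 3, hetIn = "maternal")
  expect_identical(truthHaplotypes(tr2), haps)
  # every marker heterozygous in at least one parent under default forcing
  m <- genomeFixture()
  h <- truthHaplotypes(m$truth)
  mk <- markerSites(m$map)$role == "marker"
  hetM <- h$maternal[1, mk] != h$maternal[2, mk]
  hetP <- h$paternal[1, mk] != h$paternal[2, mk]
  expect_true(all(hetM | hetP))
})

test_that("both designated AR carriers receive the shared variant heterozygously", {
  tg <- pathogenicTarget("chr2", 2e6, "A", "T", parent = "maternal",
                         inheritance = "AR",
                         partner = data.frame(chrom = "chr2", pos = 2e6,
                                              ref = "A", alt = "T"))
  map <- buildMarkerMap("chr2", 1, 4e6, nMarkers = 50, target = tg, seed = 2)
  tr <- makeParentalTruth(map, seed = 4)
  tIdx <- targetIndices(map)
  h <- truthHaplotypes(tr)
  expect_equal(sum(h$maternal[, tIdx]), 1L)
  expect_equal(sum(h$paternal[, tIdx]), 1L)
})

test_that("error-free fragments copy their source haplotype exactly", {
  fx <- familyFixture()
  fr <- simulateFragments(fx$truth, "maternal", nFragments = 200,
                          perSiteError = 0, seed = 9)
  ob <- fragmentObservations(fr)
  hap <- truthHaplotypes(fx$truth)$maternal
  src <- fragmentTable(fr)$hap[ob$fragment]
  expect_true(all(ob$allele == hap[cbind(src, ob$site)]))
})

test_that("fragment lengths and allele errors match their nominal rates", {
  fx <- familyFixture()
  fr <- simulateFragments(fx$truth, "maternal", nFragments = 5000,
                          fragLenMean = 40000, perSiteError = 0.04, seed = 21)
  lens <- fragmentTable(fr)$end - fragmentTable(fr)$start
  expect_lt(abs(mean(lens) - 40000) / 40000, 0.05)
  ob <- fragmentObservations(fr)
  hap <- truthHaplotypes(fx$truth)$maternal
  src <- fragmentTable(fr)$hap[ob$fragment]
  errRate <- mean(ob$allele != hap[cbind(src, ob$site)])
  se <- sqrt(0.04 * 0.96 / nrow(ob))
  expect_lt(abs(errRate - 0.04), 3 * se)
  # enough molecules span the target to report Table-style spanning counts
  expect_gte(mutationSpanningReads(fr, fx$map), 1L)
})

test_that("transmitted labels switch exactly at crossovers", {
  fx <- familyFixture()
  et0 <- simulateEmbryo(fx$truth, transmit = list(maternal = "risk"),
                        seed = 2)
  lab <- et0@transmitted$maternal
  expect_equal(sum(diff(lab) != 0), 0L)
  # the risk-transmitting embryo carries the target allele
  hap <- truthHaplotypes(fx$truth)$maternal
  expect_equal(hap[cbind(lab, seq_along(lab))][fx$tIdx], 1L)
  et1 <- simulateEmbryo(fx$truth, crossovers = list(maternal = 2.5e6),
                        seed = 2)
  expect_equal(sum(diff(et1@transmitted$maternal) != 0), 1L)
  # property: number of label switches equals number of crossovers
  for (k in 1:5) {
    co <- sort(sample(seq(2e5, 4.8e6, by = 1e5), k))
    et <- simulateEmbryo(fx$truth, crossovers = list(maternal = co),
                         seed = 30 + k)
    expect_equal(sum(diff(et@transmitted$maternal) != 0), k)
  }
  expect_error(simulateEmbryo(fx$truth, crossovers = list(maternal = 6e6)),
               "outside")
})

test_that("genotype calls equal truth when amplification is clean", {
  fx <- familyFixture()
  et <- simulateEmbryo(fx$truth, seed = 4)
  eg <- simulateEmbryoGenotypes(et, fx$truth, meanDepth = 200, adoRate = 0,
                                perReadError = 0, seed = 5)
  tmpl <- phaselink:::embryoTemplates(et, fx$truth)
  want <- vapply(tmpl, function(a) paste(sort(a), collapse = "/"), character(1))
  expect_identical(genotypeCalls(eg)$gt, want)
})

test_that("allele dropout turns heterozygotes into confident homozygotes", {
  fx <- familyFixture()
  et <- simulateEmbryo(fx$truth, seed = 4)
  eg <- simulateEmbryoGenotypes(et, fx$truth, meanDepth = 200,
                                adoRate = 0.99, perReadError = 0, seed = 6)
  tmpl <- phaselink:::embryoTemplates(et, fx$truth)
  hetSites <- which(vapply(tmpl, function(a) length(a) == 2 && sum(a) == 1,
                           logical(1)))
  gt <- genotypeCalls(eg)$gt[hetSites]
  expect_gt(mean(gt %in% c("0/0", "1/1")), 0.95)
})

test_that("triploid BAF concentrates near one third at AAB sites", {
  fx <- familyFixture()
  et <- simulateEmbryo(fx$truth, ploidy = "triploid", seed = 8)
  eg <- simulateEmbryoGenotypes(et, fx$truth, meanDepth = 400, adoRate = 0,
                                perReadError = 0, seed = 9)
  tmpl <- phaselink:::embryoTemplates(et, fx$truth)
  aab <- which(vapply(tmpl, function(a) length(a) == 3 && sum(a) == 1,
                      logical(1)))
  expect_gt(length(aab), 10)
  expect_lt(abs(mean(genotypeCalls(eg)$baf[aab]) - 1 / 3), 0.02)
})

test_that("window counts track local copy number, including mosaics", {
  gx <- genomeFixture()
  # diploid: empirical mean within 2% of the analytic mean at >= 1e4 windows
  big <- combineMarkerMaps(lapply(1:5, function(k)
    buildMarkerMap(sprintf("chr%d", k), 1, 4e8, 10, seed = 40 + k)))
  trBig <- makeParentalTruth(big, seed = 41)
  etBig <- simulateEmbryo(trBig, seed = 42)
  wcBig <- simulateWindowCounts(etBig, windowWidth = 2e5, meanCount = 100,
                                dispersion = 0.05, nReference = 2, seed = 43)
  expect_gte(nrow(wcBig@windows), 1e4)
  expect_lt(abs(mean(wcBig@test) - 100) / 100, 0.02)
  # trisomy: ratio 1.5 on the affected chromosome (mean over 5 seeds; a
  # single 40-window chromosome mean has sd ~0.06 of the ratio)
  et3 <- simulateEmbryo(gx$truth, ploidy = "trisomy", chrom = "chr3",
                        seed = 44)
  r3 <- sapply(1:5, function(s) {
    wc <- simulateWindowCounts(et3, seed = 44 + s)
    c(mean(wc@test[wc@windows$chrom == "chr3"]),
      mean(wc@test[wc@windows$chrom != "chr3"]))
  })
  expect_lt(abs(mean(r3[1, ]) / 100 - 1.5), 0.08)
  expect_lt(abs(mean(r3[2, ]) / 100 - 1.0), 0.05)
  # mosaic loss f = 0.30: expected ratio (2 - 0.3)/2 = 0.85
  etm <- simulateEmbryo(gx$truth, ploidy = "monosomy", chrom = "chr2",
                        mosaicFraction = 0.30, seed = 46)
  rm5 <- sapply(1:5, function(s) {
    wc <- simulateWindowCounts(etm, seed = 46 + s)
    mean(wc@test[wc@windows$chrom == "chr2"])
  })
  expect_lt(abs(mean(rm5) / 100 - 0.85), 0.06)
  # seeded determinism
  expect_identical(simulateWindowCounts(etm, seed = 47)@test,
                   simulateWindowCounts(etm, seed = 47)@test)
})
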