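# Fragment filtering, the greedy MEC phaser, haplotype signing and
# informative-SNP selection.

test_that("fragment filtering enforces quality and minimum informative sites", {
  fs <- tinyFragments(list(c(`3` = 1L),                       # one site
                           c(`1` = 0L, `2` = 1L, `3` = 0L,
                             `4` = 1L, `5` = 0L),             # five sites
                           c(`1` = 0L, `2` = 1L)),            # two sites
                      quals = list(60, 60, c(60, 10)))
  out <- filterFragments(fs, minSites = 2, minQuality = 30)
  # fragment 1 has < 2 sites; fragment 3 drops to 1 site after masking
  expect_equal(nrow(fragmentTable(out)), 1L)
  expect_equal(nrow(fragmentObservations(out)), 5L)
  out2 <- filterFragments(fs, minSites = 2, minQuality = 0)
  expect_equal(nrow(fragmentTable(out2)), 2L)
})

test_that("mecScore matches its definition and is flip-symmetric", {
  fs <- tinyFragments(list(c(`1` = 0L, `2` = 0L), c(`1` = 1L, `2` = 1L)))
  expect_equal(mecScore(fs, c(0L, 0L)), 0L)
  fs2 <- tinyFragments(list(c(`1` = 0L, `2` = 1L)))
  expect_equal(mecScore(fs2, c(0L, 0L)), 1L)
  empty <- tinyFragments(list(), nSites = 2)
  expect_equal(mecScore(empty, c(0L, 1L)), 0L)
  # observation at an unphased site is an error
  expect_error(mecScore(fs, c(0L, NA)), "unphased")
  # property: swapping haplotype A and B never changes the score
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    obs <- lapply(1:10, function(f) {
      s <- sort(sample(n, sample(2:n, 1)))
      stats::setNames(sample(0:1, length(s), replace = TRUE), s)
    })
    fs <- tinyFragments(obs, nSites = n)
    h <- sample(0:1, n, replace = TRUE)
    expect_identical(mecScore(fs, h), mecScore(fs, 1L - h))
  }
})

test_that("perfect fragments phase to the truth up to one global flip", {
  truthA <- c(0L, 1L, 1L, 0L, 1L, 0L, 0L, 1L)
  set.seed(1)
  obs <- lapply(1:30, function(f) {
    s <- sort(sample(8, sample(2:5, 1)))
    al <- if (runif(1) < 0.5) truthA[s] else 1L - truthA[s]
    stats::setNames(al, s)
  })
  fs <- tinyFragments(obs, nSites = 8)
  ph <- phaseSites(fs, 1:8)
  ps <- phasedSites(ph)
  expect_equal(length(unique(ps$block)), 1L)
  agree <- ps$hapA == truthA[ps$site]
  expect_true(all(agree) || all(!agree))
  expect_true(all(ps$conf == 1))
  expect_equal(mecScore(fs, ph), 0L)
})

test_that("disconnected fragment clusters yield separate blocks; no het sites yield none", {
  fs <- tinyFragments(list(c(`1` = 0L, `2` = 1L), c(`1` = 0L, `2` = 1L),
                           c(`5` = 1L, `6` = 0L), c(`5` = 1L, `6` = 0L)),
                      nSites = 6)
  ph <- phaseSites(fs, 1:6)
  expect_equal(length(unique(phasedSites(ph)$block)), 2L)
  expect_equal(nrow(phasedSites(phaseSites(fs, integer(0)))), 0L)
})

test_that("the greedy phaser attains the exhaustive minimum MEC on noisy instances", {
  set.seed(99)
  hits <- 0
  for (rep in 1:20) {
    n <- 10
    truthA <- sample(0:1, n, replace = TRUE)
    obs <- lapply(1:30, function(f) {
      s <- sort(sample(n, sample(2:4, 1)))
      al <- if (runif(1) < 0.5) truthA[s] else 1L - truthA[s]
      flip <- runif(length(s)) < 0.1
      al[flip] <- 1L - al[flip]
      stats::setNames(al, s)
    })
    fs <- tinyFragments(obs, nSites = n)
    ph <- phaseSites(fs, 1:n)
    if (length(unique(phasedSites(ph)$block)) > 1L) next
    if (mecScore(fs, ph) == bruteForceMEC(fs, 1:n)) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("signing labels the alt-bearing haplotype risk with the spanning-fragment consistency", {
  # 17 spanning fragments, all carrying alt on the same haplotype
  truthA <- c(0L, 1L, 0L, 1L, 1L)   # site 3 is the target, hap A carries ref
  mkObs <- function(n, hapB = TRUE, altOk = rep(TRUE, n)) {
    lapply(1:n, function(f) {
      al <- if (hapB) 1L - truthA else truthA
      if (!altOk[f]) al[3] <- 1L - al[3]
      stats::setNames(al, 1:5)
    })
  }
  map <- buildMarkerMap("chr1", 1, 1e6,
                        nMarkers = 4,
                        target = pathogenicTarget("chr1", 5e5, "A", "T"),
                        seed = 1)
  # hap B = complement of truthA carries allele 1 at site 3
  fs <- tinyFragments(c(mkObs(9, hapB = TRUE), mkObs(8, hapB = FALSE)),
                      nSites = 5)
  ph <- phaseSites(fs, 1:5)
  sg <- signHaplotypes(ph, fs, map, carrierGenotype = "0/1",
                       parent = "maternal", targetSite = 3L)
  expect_equal(signingCall(sg), "signed")
  expect_equal(sg@spanningReads, 17L)
  expect_equal(sg@consistency, 1.0)
  ps <- phasedSites(sg)
  riskAlleleAtTarget <- if (riskHaplotype(sg) == "A")
    ps$hapA[ps$site == 3] else 1L - ps$hapA[ps$site == 3]
  expect_equal(riskAlleleAtTarget, 1L)

  # 9 of 10 spanning fragments consistent: signed at consistency 0.9
  fs2 <- tinyFragments(c(mkObs(5, hapB = TRUE, altOk = c(TRUE, TRUE, TRUE,
                                                         TRUE, FALSE)),
                         mkObs(5, hapB = FALSE)), nSites = 5)
  ph2 <- phaseSites(fs2, 1:5)
  sg2 <- signHaplotypes(ph2, fs2, map, "0/1", targetSite = 3L)
  expect_equal(signingCall(sg2), "signed")
  expect_equal(sg2@consistency, 0.9)

  # an even split between haplotypes is an explicit no-call: the target
  # allele is uncorrelated with the haplotype, so half the spanning
  # fragments contradict any assignment
  half <- c(mkObs(2, hapB = TRUE), mkObs(2, hapB = TRUE, altOk = c(FALSE, FALSE)),
            mkObs(3, hapB = FALSE), mkObs(3, hapB = FALSE, altOk = rep(FALSE, 3)))
  fsHalf <- tinyFragments(half, nSites = 5)
  sg3 <- signHaplotypes(phaseSites(fsHalf, 1:5), fsHalf, map, "0/1",
                        targetSite = 3L)
  expect_equal(signingCall(sg3), "nocall")

  # fewer spanning fragments than required: no-call
  few <- tinyFragments(mkObs(3, hapB = TRUE), nSites = 5)
  sgf <- signHaplotypes(phaseSites(few, 1:5), few, map, "0/1",
                        targetSite = 3L, minSpanReads = 5L)
  expect_equal(signingCall(sgf), "nocall")

  # a homozygous carrier cannot be signed
  expect_error(signHaplotypes(ph, fs, map, "0/0", targetSite = 3L),
               "heterozygous")
  # target outside any block is the unsigned error state
  expect_error(signHaplotypes(ph, fs, map, "0/1", targetSite = 5000L),
               class = "phaselink_unsigned")
})

test_that("informative SNPs require a homozygous other parent inside the window", {
  fx <- familyFixture()
  sg <- fx$signed
  info <- informativeSnps(sg)
  expect_gt(nrow(info), 50)
  s <- markerSites(fx$map)
  otherGt <- truthGenotypes(fx$truth)$paternal
  # every selected site: father homozygous, inside +/- 2 Mb, mother phased het
  expect_true(all(otherGt[info$site] %in% c("0/0", "1/1")))
  expect_true(all(info$distance <= 2e6))
  expect_true(all(info$site %in% phasedSites(sg)$site))
  # double-het sites are excluded
  bothHet <- which(substr(otherGt, 1, 1) != substr(otherGt, 3, 3))
  expect_length(intersect(info$site, bothHet), 0L)
  # two-sided counts reported the way clinical workups print them
  sm <- informativeSummary(sg)
  expect_named(sm$counts, c("upstream", "downstream"))
  expect_true(all(sm$counts > 0))
  # the risk-linked allele sits on the haplotype that carries the target
  hap <- truthHaplotypes(fx$truth)$maternal
  riskHapIdx <- which(hap[, fx$tIdx] == 1L)
  expect_equal(info$riskAllele, unname(hap[riskHapIdx, info$site]))
})

test_that("mutation-spanning read counting requires both overlap and an observation", {
  map <- buildMarkerMap("chr1", 1, 1e6, nMarkers = 10,
                        target = pathogenicTarget("chr1", 5e5, "A", "T"),
                        seed = 3)
  tIdx <- targetIndices(map)
  # 16 fragments overlap and observe the target; 4 overlap but are masked
  obs <- c(replicate(16, stats::setNames(c(0L, 0L), c(1, tIdx)),
                     simplify = FALSE),
           replicate(4, stats::setNames(0L, "1"), simplify = FALSE))
  fs <- tinyFragments(obs, nSites = 11, starts = rep(0, 20),
                      ends = rep(1e6, 20))
  expect_equal(mutationSpanningReads(fs, map), 16L)
  none <- tinyFragments(list(stats::setNames(0L, "1")), nSites = 11,
                        starts = 0, ends = 10)
  expect_equal(mutationSpanningReads(none, map), 0L)
})
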