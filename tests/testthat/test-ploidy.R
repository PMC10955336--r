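# Chromosome-level heterozygosity / BAF Z scores and the genome-wide
# ploidy call.

ploidyFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gx <- genomeFixture()
      panel <- lapply(1:12, function(k) {
        et <- simulateEmbryo(gx$truth, seed = 700 + k)
        simulateEmbryoGenotypes(et, gx$truth, embryoId = sprintf("P%d", k),
                                seed = 720 + k)
      })
      cache <<- list(gx = gx, panel = panel, stats = panelStats(panel))
    }
    cache
  }
})

test_that("z-scores follow their definition and zero panel spread is an error", {
  stats <- data.frame(chrom = c("chr1", "chr2"), callable = 200L,
                      hetProp = c(0.4, 0.4 + 3 * 0.02),
                      bafDev = c(0.07, 0.07), informative = TRUE)
  panel <- data.frame(chrom = c("chr1", "chr2"), muHet = 0.4, sdHet = 0.02,
                      muBaf = 0.07, sdBaf = 0.01, n = 20)
  rep <- zScores(stats, panel)
  cs <- chromosomeStats(rep)
  expect_equal(cs$zHet, c(0, 3))
  expect_equal(cs$flagged, c(FALSE, TRUE))
  expect_equal(ploidyCall(rep), "normal")  # one chromosome is not genome-wide
  bad <- panel; bad$sdHet <- 0
  expect_error(zScores(stats, bad), "larger or noisier")
})

test_that("haploid and triploid embryos are recognized genome-wide; diploids are not", {
  fx <- ploidyFixture()
  run <- function(ploidy, seed) {
    et <- simulateEmbryo(fx$gx$truth, ploidy = ploidy, seed = seed)
    eg <- simulateEmbryoGenotypes(et, fx$gx$truth, embryoId = "T",
                                  seed = seed + 1)
    zScores(chromStats(eg), fx$stats)
  }
  hap <- run("haploid", 801)
  expect_equal(ploidyCall(hap), "haploid-suspect")
  expect_gte(median(abs(chromosomeStats(hap)$z)), 3)
  # haploids keep only error-driven heterozygous calls
  expect_lt(max(chromosomeStats(hap)$hetProp), 0.05)

  tri <- run("triploid", 803)
  expect_equal(ploidyCall(tri), "triploid-suspect")
  expect_equal(tri@karyotype, "69,XNN")
  expect_gt(median(chromosomeStats(tri)$bafDev), 0.12)

  # diploid calibration: flag rate pooled across embryos stays below 5%
  flags <- unlist(lapply(1:15, function(k) {
    dip <- run("diploid", 900 + 2 * k)
    expect_equal(ploidyCall(dip), "normal")
    chromosomeStats(dip)$flagged
  }))
  expect_lt(mean(flags), 0.05)

  # one trisomic chromosome must never trigger a genome-wide ploidy call
  et <- simulateEmbryo(fx$gx$truth, ploidy = "trisomy", chrom = "chr2",
                       seed = 807)
  eg <- simulateEmbryoGenotypes(et, fx$gx$truth, embryoId = "T", seed = 808)
  expect_equal(ploidyCall(zScores(chromStats(eg), fx$stats)), "normal")
})

test_that("the genome-wide call is invariant to chromosome order", {
  fx <- ploidyFixture()
  et <- simulateEmbryo(fx$gx$truth, ploidy = "triploid", seed = 811)
  eg <- simulateEmbryoGenotypes(et, fx$gx$truth, embryoId = "T", seed = 812)
  st <- chromStats(eg)
  perm <- st[sample(nrow(st)), ]
  expect_equal(ploidyCall(zScores(perm, fx$stats)),
               ploidyCall(zScores(st, fx$stats)))
})

test_that("chromosomes below the callable floor are uninformative, not wrong", {
  fx <- ploidyFixture()
  et <- simulateEmbryo(fx$gx$truth, seed = 821)
  eg <- simulateEmbryoGenotypes(et, fx$gx$truth, meanDepth = 3,
                                embryoId = "lowdp", seed = 822)
  st <- chromStats(eg, depthFloor = 8, minCallable = 50)
  expect_true(all(!st$informative))
})
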