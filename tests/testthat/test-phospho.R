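mkPairs <- function(u, t) {
  data.frame(spot_id = paste0("s", seq_along(u)), vol_untreated = u,
             vol_treated = t, stringsAsFactors = FALSE)
}

test_that("classification applies a strict ratio threshold", {
  calls <- ppaseRatioClassify(mkPairs(c(1.6, 1.5, 1.0), c(1, 1, 1)))
  expect_identical(calls$flagged, c(TRUE, FALSE, FALSE))
  expect_identical(calls$shift_class, c("partial", "none", "none"))
  # treated volume at/below the floor: fully-shifted branch, no division
  calls2 <- ppaseRatioClassify(mkPairs(c(5, 0.005), c(0, 0)),
                               detectionFloor = 0.01)
  expect_identical(nrow(calls2), 1L)  # sub-floor untreated spot: no call
  expect_identical(calls2$shift_class, "fully_shifted")
  expect_true(calls2$flagged)
  # raising the threshold never increases the flagged count
  u <- runif(50, 0.5, 3); t <- rep(1, 50)
  n15 <- sum(ppaseRatioClassify(mkPairs(u, t), 1.5)$flagged)
  n20 <- sum(ppaseRatioClassify(mkPairs(u, t), 2.0)$flagged)
  expect_lte(n20, n15)
})

test_that("noise-free contrast flags exactly the occupancy > 1/3 spots", {
  m <- generateProteome(nProteins = 150, seed = 61)
  design <- gelDesign("x", phRanges = list(c(0.5, 13.5)))
  contrast <- simulatePpaseContrast(m, design, efficiency = 1, seed = 2)
  calls <- ppaseRatioClassify(contrast, threshold = 1.5)
  # algebraic oracle: ratio = 1/(1 - o) > 1.5 iff o > 1/3
  spots <- calls[calls$vol_untreated > 0, ]
  expect_identical(spots$flagged, spots$phospho_share > 1 / 3)
  # and the realized ratio follows 1/(1 - e*o) exactly in the noise-free case
  finite <- is.finite(spots$ratio)
  expect_equal(spots$ratio[finite],
               1 / (1 - spots$phospho_share[finite]), tolerance = 1e-9)
  # partial efficiency version of the same algebra
  e <- 0.7
  c2 <- simulatePpaseContrast(m, design, efficiency = e, seed = 2)
  k2 <- ppaseRatioClassify(c2)
  f2 <- is.finite(k2$ratio) & k2$vol_untreated > 0
  expect_equal(k2$ratio[f2], 1 / (1 - e * k2$phospho_share[f2]),
               tolerance = 1e-9)
  # monotone in occupancy: flagged set at higher occupancy is a superset
  expect_true(all(k2$flagged[f2][k2$phospho_share[f2] > 1 / (1.5 * e) * (1.5 - 1)]))
})

test_that("contrast conserves total abundance and empties o = 1 spots", {
  m <- generateProteome(nProteins = 80, seed = 63)
  design <- gelDesign("x", phRanges = list(c(0.5, 13.5)))
  contrast <- simulatePpaseContrast(m, design, efficiency = 1, seed = 3)
  expect_equal(sum(contrast$vol_treated), sum(contrast$vol_untreated),
               tolerance = 1e-9)
  # a phospho-free model gives ratio 1 everywhere
  m0 <- generateProteome(nProteins = 30, phosphoFraction = 0, seed = 64)
  c0 <- simulatePpaseContrast(m0, design, seed = 4)
  expect_equal(c0$vol_treated, c0$vol_untreated)
  # occupancy 1 at full efficiency leaves nothing at the phospho position
  pairs <- mkPairs(10, 10 * (1 - 1 * 1))
  expect_identical(ppaseRatioClassify(pairs)$shift_class, "fully_shifted")
})

test_that("the headline phospho fraction rounds half-up to integer percent", {
  f <- phosphoFraction(81, 1923)
  expect_identical(f$percent, 4)
  expect_equal(f$unrounded, 4.2121, tolerance = 1e-4)
  expect_identical(phosphoFraction(0, 100)$percent, 0)
  expect_identical(phosphoFraction(100, 100)$percent, 100)
  expect_identical(phosphoFraction(25, 1000)$percent, 3)  # 2.5 rounds up
  expect_error(phosphoFraction(1, 0), "total")
})

test_that("spot-pair stoichiometry reports ratios and one-sided labels", {
  expect_equal(spotPairStoichiometry(2.7, 1.0)$ratio, 2.7)
  expect_identical(spotPairStoichiometry(2.7, 1.0)$label, "two-sided")
  expect_identical(spotPairStoichiometry(2.7, NA)$label, "phospho-only")
  expect_identical(spotPairStoichiometry(NA, 1)$label, "dephospho-only")
  # occupancy algebra: splitting one form's population o / (1 - o)
  o <- 0.62; A <- 40
  expect_equal(spotPairStoichiometry(o * A, (1 - o) * A)$ratio, o / (1 - o))
})

test_that("phosphopeptide/iBAQ ratios sit below 1 at low stoichiometry", {
  expect_equal(ibaqPpeptideRatio(
    data.frame(accession = "P1", intensity = 5),
    data.frame(accession = "P1", ibaq = 10))$ratios$ratio, 0.5)
  expect_equal(ibaqPpeptideRatio(
    data.frame(accession = "P1", intensity = 10),
    data.frame(accession = "P1", ibaq = 10))$ratios$ratio, 1)
  expect_message(r <- ibaqPpeptideRatio(
    data.frame(accession = c("P1", "P9"), intensity = c(5, 5)),
    data.frame(accession = "P1", ibaq = 10)), "skipped")
  expect_identical(r$nSkipped, 1L)

  # simulation: low occupancy, penalty-free detection
  m <- generateProteome(nProteins = 120, occupancyRange = c(0.02, 0.25),
                        seed = 71)
  nm <- noiselessModel(phosphoPenalty = 1)
  a <- sampleReplicateAbundances(m, 1, 1, nm, "shotgun", seed = 5)
  obs <- simulateShotgunRuns(m, a, shotgunParams(), nm, seed = 6,
                             fullDetection = TRUE)
  ib <- computeIbaq(obs, m)
  ppep <- ProteoformSim:::.phosphoIntensities(obs)
  res <- ibaqPpeptideRatio(ppep, ib)
  expect_gte(res$fractionBelow1, 0.9)
})
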