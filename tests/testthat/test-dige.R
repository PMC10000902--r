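# two-protein toy with forms at controlled coordinates
toyDigeModel <- function() {
  sA <- "MKDDEEAAAKSSSTTTKCCCAAAKDDDEEEKAAAGGGKTTTAAAK"
  sB <- "MKHHRRKAAAKYYYKGGGAAAKHHHRRRKAAATTTKGGGAAAKHH"
  proteins <- data.frame(accession = c("P1", "P2"),
                         sequence = c(sA, sB), stringsAsFactors = FALSE)
  proteoforms <- rbind(formRow("P1.1", "P1", sA, abundance = 100),
                       formRow("P1.2", "P1", sA, abundance = 40),
                       formRow("P2.1", "P2", sB, abundance = 10))
  makeModel(proteins, proteoforms)
}

test_that("indistinguishable proteoforms merge into one spot", {
  m <- toyDigeModel()
  design <- gelDesign("s1", phRanges = list(c(3, 13)))
  spots <- formSpots(m, design)
  # P1.1 and P1.2 share sequence, hence identical (pI, MW): one spot
  expect_identical(nrow(spots), 2L)
  merged <- spots[spots$n_proteoforms == 2L, ]
  expect_equal(merged$base_volume, 140)
  expect_setequal(strsplit(merged$proteoform_ids, ";")[[1]],
                  c("P1.1", "P1.2"))
})

test_that("well-separated proteoforms map one-to-one onto spots", {
  m <- generateProteome(nProteins = 25, meanProteoforms = 1,
                        phosphoFraction = 0, seed = 33)
  design <- gelDesign("s1", phRanges = list(c(0.5, 13.5)),
                      deltaPi = 1e-6, deltaMwRel = 1e-9)
  spots <- formSpots(m, design)
  expect_identical(nrow(spots), nProteoforms(m))
  expect_true(all(spots$n_proteoforms == 1L))
})

test_that("proteoforms outside every pH range are dropped", {
  m <- generateProteome(nProteins = 50, seed = 17)
  spots <- formSpots(m, gelDesign("s1"))  # pH 4-7 and 6-9
  expect_true(all(spots$pi >= 4 & spots$pi <= 9))
  inRange <- sum(proteoforms(m)$pi >= 4 & proteoforms(m)$pi <= 9)
  expect_lte(nrow(spots), inRange)
  # top-down resolution: at least as many spots as parent proteins in range
  expect_gte(nrow(spots),
             length(unique(proteoforms(m)$accession[
               proteoforms(m)$pi >= 4 & proteoforms(m)$pi <= 9])))
})

test_that("zero noise and certain detection reproduce true volumes", {
  m <- generateProteome(nProteins = 30, seed = 7)
  quiet <- noiselessModel()
  a <- sampleReplicateAbundances(m, 1, 2, quiet, "dige", seed = 1)
  design <- gelDesign(colnames(a))
  spots <- formSpots(m, design)
  obs <- simulateGels(spots, a, design, quiet, seed = 2, jitterPi = 0,
                      jitterMwRel = 0)
  one <- obs[obs$sample == "b1_t1", ]
  expect_equal(stats::setNames(one$raw_volume, one$spot_id)[spots$spot_id],
               stats::setNames(spots$base_volume, spots$spot_id),
               tolerance = 1e-12)
  # conservation: total observed volume = total in-range proteoform abundance
  expect_equal(sum(one$raw_volume), sum(spots$base_volume), tolerance = 1e-9)

  # channel gain scales raw volumes but cancels in normalized volumes
  obsG <- simulateGels(spots, a, design, quiet, seed = 2, jitterPi = 0,
                       jitterMwRel = 0, gains = c(Cy3 = 10))
  g3 <- obsG[obsG$channel == "Cy3", ]
  n3 <- obs[obs$channel == "Cy3", ]
  expect_equal(g3$raw_volume, n3$raw_volume * 10)
  expect_equal(g3$norm_volume, n3$norm_volume, tolerance = 1e-12)
})

test_that("standardized abundance is the within-gel ratio to the IS", {
  obs <- data.frame(
    gel_id = "gel1", channel = c("Cy3", "Cy3", "Cy2", "Cy2"),
    sample = c("s1", "s1", "IS", "IS"), ph_range = "4-7",
    spot_id = c("a", "b", "a", "b"), pi = 5, mw_kda = 30,
    raw_volume = c(20, 10, 10, 10),
    norm_volume = c(0.002, 0.001, 0.001, 0.001), stringsAsFactors = FALSE)
  design <- gelDesign("s1")
  sa <- standardizeAbundance(obs, design)
  expect_equal(sa$sa[sa$spot_id == "a"], 2.0)
  expect_equal(sa$sa[sa$spot_id == "b"], 1.0)
  # scaling one channel's raw volumes leaves SA unchanged (norm invariance)
  obs2 <- obs
  obs2$raw_volume[obs2$channel == "Cy3"] <- obs$raw_volume[obs$channel == "Cy3"] * 7
  expect_equal(standardizeAbundance(obs2, design)$sa, sa$sa)
  # IS spot missing: SA undefined, propagates as missing
  obs3 <- obs[-3, ]
  expect_true(is.na(standardizeAbundance(obs3, design)$sa[1]))
})

test_that("a sample identical to the pool has SA 1 everywhere", {
  m <- generateProteome(nProteins = 25, seed = 9)
  quiet <- noiselessModel()
  a <- sampleReplicateAbundances(m, 1, 2, quiet, "dige", seed = 1)
  design <- gelDesign(colnames(a))
  spots <- formSpots(m, design)
  obs <- simulateGels(spots, a, design, quiet, seed = 3)
  sa <- standardizeAbundance(obs, design)
  expect_true(all(abs(sa$sa - 1) < 1e-12))
})

test_that("matching recovers ground-truth spot identity under jitter", {
  m <- generateProteome(nProteins = 80, seed = 23)
  quiet <- noiselessModel()
  a <- sampleReplicateAbundances(m, 1, 6, quiet, "dige", seed = 2)
  design <- gelDesign(colnames(a))
  spots <- formSpots(m, design)
  obs <- simulateGels(spots, a, design, quiet, seed = 4)
  sa <- standardizeAbundance(obs, design)
  matched <- matchSpots(sa, design)
  # with full detection and sub-tolerance jitter everything is matched ...
  expect_gte(mean(stats::complete.cases(matched@sa)), 0.99)
  # ... and the matched SA values agree with the truth-keyed values
  byTruth <- tapply(sa$sa, list(sa$spot_id, sa$sample), mean)
  common <- intersect(rownames(matched@sa), rownames(byTruth))
  agree <- matched@sa[common, colnames(byTruth)] == byTruth[common, ]
  expect_gte(mean(agree, na.rm = TRUE), 0.99)
})

test_that("identical observation tables match 100%", {
  m <- generateProteome(nProteins = 30, seed = 3)
  quiet <- noiselessModel()
  a <- sampleReplicateAbundances(m, 1, 3, quiet, "dige", seed = 1)
  design <- gelDesign(colnames(a))
  spots <- formSpots(m, design)
  obs <- simulateGels(spots, a, design, quiet, seed = 1, jitterPi = 0,
                      jitterMwRel = 0)
  sa <- standardizeAbundance(obs, design)
  matched <- matchSpots(sa, design)
  expect_true(all(stats::complete.cases(matched@sa)))
  # a spot absent from one replicate leaves the 100%-matched subset
  sa2 <- sa[!(sa$sample == "b1_t2" & sa$spot_id == sa$spot_id[1]), ]
  matched2 <- matchSpots(sa2, design)
  expect_identical(sum(stats::complete.cases(matched2@sa)),
                   sum(stats::complete.cases(matched@sa)) - 1L)
})

test_that("detection probability p over k replicates gives ~p^k full matches", {
  m <- generateProteome(nProteins = 150, meanProteoforms = 1,
                        phosphoFraction = 0, seed = 29)
  p <- 0.8; k <- 4L
  nm <- noiseModel(sigmaTechDige = 0,
                   detection = list(digeFloor = p, digeCeiling = p,
                                    ph69Penalty = 1))
  a <- sampleReplicateAbundances(m, 1, k, nm, "dige", seed = 5)
  design <- gelDesign(colnames(a))
  spots <- formSpots(m, design)
  obs <- simulateGels(spots, a, design, nm, seed = 6)
  sa <- standardizeAbundance(obs, design)
  # count usable SA values per ground-truth spot
  perSpot <- tapply(!is.na(sa$sa), sa$spot_id, sum)
  cnt <- perSpot[spots$spot_id]
  cnt[is.na(cnt)] <- 0
  fullFrac <- mean(cnt == k)
  # binomial oracle: k independent sample detections plus one IS detection
  # per gel (k/2 gels; the IS draw is shared by a gel's two channels)
  expected <- p^k * p^(k / 2)
  se <- sqrt(expected * (1 - expected) / nrow(spots))
  expect_lt(abs(fullFrac - expected), 5 * se + 0.02)
})

test_that("median spot CV rises with technical noise", {
  m <- generateProteome(nProteins = 120, seed = 31)
  meds <- vapply(c(0.02, 0.08, 0.25), function(sg) {
    nm <- noiseModel(sigmaTechDige = sg,
                     detection = list(digeFloor = 1, digeCeiling = 1,
                                      ph69Penalty = 1))
    a <- sampleReplicateAbundances(m, 1, 6, nm, "dige", seed = 7)
    design <- gelDesign(colnames(a))
    spots <- formSpots(m, design)
    sa <- standardizeAbundance(simulateGels(spots, a, design, nm, seed = 8),
                               design)
    matched <- matchSpots(sa, design)
    suppressMessages(summarizeVariation(matched@sa)$median)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("spot volume reconstruction averages replicates", {
  mk <- function(v) {
    methods::new("MatchedSpotTable",
                 sa = matrix(1, 1, length(v)),
                 normVolume = matrix(v, 1),
                 spots = data.frame(spot_id = "s", ph_range = "4-7", pi = 5,
                                    mw_kda = 30, stringsAsFactors = FALSE))
  }
  expect_equal(reconstructSpotVolume(mk(c(5, 5, 5)))$spot_size, 5)
  expect_equal(reconstructSpotVolume(mk(c(1, 2, 3)))$spot_size, 2)
  # a missing entry excludes the spot rather than being imputed
  expect_identical(nrow(reconstructSpotVolume(mk(c(1, NA, 3)))), 0L)
})
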