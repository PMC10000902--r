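# toy model where a truncation shares peptides with its parent
toyShotgunModel <- function() {
  sA <- "MAAAEEEKCCCDDDKGGGFFFKHHHIIIKLLLMMMK"
  sB <- "MNNNPPPKQQQSSSKTTTVVVKWWWYYYKAAAGGGK"
  proteins <- data.frame(accession = c("A1", "B1"), sequence = c(sA, sB),
                         stringsAsFactors = FALSE)
  frag <- substr(sA, 9, 36)  # loses the first tryptic peptide only
  proteoforms <- rbind(
    formRow("A1.1", "A1", sA, abundance = 100),
    formRow("A1.2", "A1", frag, start = 9L, end = 36L, type = "cleavage",
            abundance = 50),
    formRow("B1.1", "B1", sB, abundance = 10))
  makeModel(proteins, proteoforms)
}

quietRuns <- function(model, nRuns = 1L, seed = 1L) {
  quiet <- noiselessModel()
  a <- sampleReplicateAbundances(model, 1, nRuns, quiet, "shotgun",
                                 seed = seed)
  simulateShotgunRuns(model, a, shotgunParams(), quiet, seed = seed + 1,
                      fullDetection = TRUE)
}

test_that("peptide intensities are proteoform sums in the zero-noise limit", {
  m <- toyShotgunModel()
  obs <- quietRuns(m)
  # a peptide shared by the full-length and truncated proteoform sums both
  shared <- obs[obs$sequence == "CCCDDDK", ]
  expect_equal(shared$intensity, 150)
  expect_setequal(strsplit(shared$proteoform_ids, ";")[[1]],
                  c("A1.1", "A1.2"))
  expect_equal(obs$intensity[obs$sequence == "MAAAEEEK"], 100)
  expect_equal(obs$intensity[obs$sequence == "QQQSSSK"], 10)
})

test_that("protein inference collapses all proteoforms of an accession", {
  m <- generateProteome(nProteins = 5, meanProteoforms = 3, seed = 55)
  obs <- quietRuns(m)
  groups <- inferProteinGroups(obs, m)
  expect_identical(length(unique(groups$accession)), 5L)
  expect_lte(length(unique(groups$accession)), nProteoforms(m))
  # per-group peptide count = distinct detected sequences of the accession
  one <- groups[groups$accession == groups$accession[1], ][1, ]
  asg <- ProteoformSim:::.peptideAssignment(obs)
  expect_identical(one$n_peptides,
                   length(unique(asg$sequence[asg$accession == one$accession])))
})

test_that("shared peptides go to the accession with maximal evidence", {
  # brute-force oracle on a 3-protein toy with one shared peptide
  obs <- data.frame(
    run_id = "r1",
    sequence = c("AAAAAAK", "CCCCCCK", "DDDDDDK", "EEEEEEK", "SHAREDK"),
    mod_state = "none", intensity = c(4, 3, 2, 1, 5), quantified = TRUE,
    loc_prob = NA_real_,
    accessions = c("P01", "P01", "P01", "P02", "P01;P02;P03"),
    proteoform_ids = "x", stringsAsFactors = FALSE)
  asg <- ProteoformSim:::.peptideAssignment(obs)
  # exhaustive evidence count: P01 has 4 distinct peptides, P02 2, P03 1
  expect_identical(asg$accession[asg$sequence == "SHAREDK"], "P01")
  groups <- inferProteinGroups(obs)
  expect_identical(groups$n_peptides[groups$accession == "P01"], 4L)
  expect_false("P03" %in% groups$accession)
})

test_that("LFQ is a plain sum for one run and scale-invariant across runs", {
  m <- toyShotgunModel()
  obs <- quietRuns(m)
  lfq <- computeLfq(obs)
  asg <- ProteoformSim:::.peptideAssignment(obs)
  sums <- tapply(obs$intensity, asg$accession[match(obs$sequence,
                                                    asg$sequence)], sum)
  expect_equal(lfq$lfq[match(names(sums), lfq$accession)], as.vector(sums))

  obs2 <- quietRuns(m, nRuns = 2)
  lfq2 <- computeLfq(obs2)
  obs10 <- obs2
  obs10$intensity[obs10$run_id == "b1_t2"] <-
    obs10$intensity[obs10$run_id == "b1_t2"] * 10
  lfq10 <- computeLfq(obs10)
  expect_equal(lfq10$lfq, lfq2$lfq, tolerance = 1e-12)
})

test_that("two-run normalization matches the hand-computed median ratio", {
  obs <- data.frame(
    run_id = rep(c("r1", "r2"), each = 3),
    sequence = rep(c("AAAAAAK", "CCCCCCK", "DDDDDDK"), 2),
    mod_state = "none",
    intensity = c(100, 200, 300, 50, 150, 120), quantified = TRUE,
    loc_prob = NA_real_, accessions = "P01", proteoform_ids = "P01.1",
    stringsAsFactors = FALSE)
  # hand: ratios r1/r2 = 2, 4/3, 2.5; median = 2; r2 scaled by 2
  lfq <- computeLfq(obs, referenceRun = "r1")
  expect_equal(lfq$lfq[lfq$run_id == "r1"], 600)
  expect_equal(lfq$lfq[lfq$run_id == "r2"], 2 * (50 + 150 + 120))
})

test_that("iBAQ divides by the theoretical peptide count", {
  obs <- data.frame(
    run_id = "r1", sequence = c("AAAAAAK", "CCCCCCK"), mod_state = "none",
    intensity = c(30, 10), quantified = TRUE, loc_prob = NA_real_,
    accessions = "T1", proteoform_ids = "T1.1", stringsAsFactors = FALSE)
  # canonical sequence with 4 measurable tryptic peptides
  model <- makeModel(
    data.frame(accession = "T1",
               sequence = "AAAAAAKCCCCCCKDDDDDDKEEEEEEK",
               stringsAsFactors = FALSE),
    formRow("T1.1", "T1", "AAAAAAKCCCCCCKDDDDDDKEEEEEEK"))
  ib <- computeIbaq(obs, model)
  expect_identical(ib$n_theoretical, 4L)
  expect_equal(ib$ibaq, 40 / 4)
  expect_lte(ib$ibaq, ib$intensity_sum)
})

test_that("stochastic DDA misses low-intensity peptides more often", {
  m <- generateProteome(nProteins = 60, seed = 77)
  nm <- noiseModel()
  a <- sampleReplicateAbundances(m, 1, 2, nm, "shotgun", seed = 3)
  obs <- simulateShotgunRuns(m, a, shotgunParams(), nm, seed = 4)
  # lowering the detection midpoint reduces missingness
  nmLow <- noiseModel(detection = list(shotgunMid = log(20)))
  obsLow <- simulateShotgunRuns(m, a, shotgunParams(), nmLow, seed = 4)
  expect_gt(nrow(obsLow), nrow(obs))
  # reproducibility accounting follows the binomial expectation
  p <- 0.7
  nmP <- noiseModel(detection = list(shotgunFloor = p, shotgunCeiling = p))
  k <- 4L
  aP <- sampleReplicateAbundances(m, 1, k, noiselessModel(), "shotgun",
                                  seed = 5)
  obsP <- simulateShotgunRuns(m, aP, shotgunParams(),
                              noiseModel(sigmaPeptide = 0,
                                         sigmaIonization = 0,
                                         detection = list(shotgunFloor = p,
                                                          shotgunCeiling = p)),
                              seed = 6)
  perPep <- table(paste(obsP$sequence, obsP$mod_state))
  nUniverse <- nrow(ProteoformSim:::.peptideUniverse(m, shotgunParams()$rule))
  dt <- ProteoformSim:::.peptideUniverse(m, shotgunParams()$rule)
  nDistinct <- length(unique(paste(dt$sequence, dt$mod_state)))
  fullFrac <- sum(perPep == k) / nDistinct
  se <- sqrt(p^k * (1 - p^k) / nDistinct)
  expect_lt(abs(fullFrac - p^k), 5 * se + 0.02)
})

test_that("phosphopeptide accounting is exact set algebra", {
  mkObs <- function(seqs, run = "r1") {
    n <- length(seqs)
    data.frame(run_id = run, sequence = seqs, mod_state = "phospho",
               intensity = 1, quantified = TRUE, loc_prob = 0.9,
               accessions = paste0("P", seq_len(n)), proteoform_ids = "x",
               stringsAsFactors = FALSE)
  }
  u <- mkObs(c("AAAK", "CCCK", "DDDK"))
  t1 <- mkObs(c("EEEK", "FFFK"))
  acc <- phosphositeAccounting(u, t1)
  expect_identical(acc$both, 0L)
  expect_identical(acc$only_untreated, 3L)
  expect_identical(acc$only_treated, 2L)
  accSame <- phosphositeAccounting(u, u)
  expect_identical(accSame$both, 3L)
  expect_identical(accSame$only_untreated, 0L)
  # 10-peptide toy against brute-force set algebra
  set.seed(1)
  su <- paste0(LETTERS[1:8], "K"); st <- paste0(LETTERS[4:10], "K")
  acc10 <- phosphositeAccounting(mkObs(su), mkObs(st))
  expect_identical(acc10$both, length(intersect(su, st)))
  expect_identical(acc10$only_untreated, length(setdiff(su, st)))
  expect_identical(acc10$only_treated, length(setdiff(st, su)))
  # localization threshold filters the localized/quantified sets
  uLow <- u; uLow$loc_prob <- 0.5
  accLow <- phosphositeAccounting(uLow, t1)
  expect_identical(unname(accLow$untreated[["localized"]]), 0L)
  expect_identical(unname(accLow$untreated[["detected"]]), 3L)
})
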