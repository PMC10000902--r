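test_that("generation is deterministic and honours degenerate configs", {
  m1 <- generateProteome(nProteins = 30, seed = 5)
  m2 <- generateProteome(nProteins = 30, seed = 5)
  expect_identical(proteoforms(m1), proteoforms(m2))
  expect_identical(proteins(m1), proteins(m2))
  m3 <- generateProteome(nProteins = 30, seed = 6)
  expect_false(identical(proteoforms(m1), proteoforms(m3)))

  noPhos <- generateProteome(nProteins = 40, phosphoFraction = 0, seed = 2)
  expect_true(all(proteoforms(noPhos)$n_phospho == 0L))
  expect_identical(nrow(modifications(noPhos)), 0L)
  expect_error(generateProteome(nProteins = 0), "configuration")
  expect_error(generateProteome(nProteins = 10, phosphoFraction = 2),
               "configuration")
})

test_that("proteoform counts and abundances match the configured model", {
  m <- generateProteome(nProteins = 10000, seed = 91)
  perProtein <- table(proteoforms(m)$accession)
  expect_gt(mean(perProtein), 2.9)
  expect_lt(mean(perProtein), 3.1)
  # wide dynamic range: > 3 orders of magnitude
  ab <- proteoforms(m)$base_abundance
  expect_gt(log10(max(ab) / min(ab)), 3)
  # tryptic sites frequent enough for measurable peptides
  seqs <- proteins(m)$sequence
  krRate <- sum(nchar(seqs) - nchar(gsub("[KR]", "", seqs))) /
    sum(nchar(seqs))
  expect_gt(krRate, 1 / 30)
  # truncations are contiguous subsequences of the parent
  pf <- proteoforms(m)
  cleaved <- pf[pf$form_type == "cleavage", ][1:50, ]
  parent <- proteins(m)$sequence[match(cleaved$accession,
                                       proteins(m)$accession)]
  expect_identical(substr(parent, cleaved$start, cleaved$end),
                   cleaved$sequence)
})

test_that("replicate abundances follow the bio/tech hierarchy", {
  m <- generateProteome(nProteins = 40, seed = 3)
  quiet <- noiselessModel()
  a0 <- sampleReplicateAbundances(m, 2, 3, quiet, "dige", seed = 1)
  expect_true(all(a0 > 0))
  expect_equal(unname(a0[, 1]), proteoforms(m)$base_abundance)
  expect_true(all(a0 == a0[, 1]))  # zero noise: every replicate = base

  # technical replicates share their biological draw
  bioOnly <- noiseModel(sigmaTechDige = 0, sigmaBioDige = 0.5)
  a1 <- sampleReplicateAbundances(m, 2, 3, bioOnly, "dige", seed = 2)
  expect_equal(a1[, "b1_t1"], a1[, "b1_t3"])
  expect_false(isTRUE(all.equal(a1[, "b1_t1"], a1[, "b2_t1"])))

  a2 <- sampleReplicateAbundances(m, 1, 6, seed = 9)
  a3 <- sampleReplicateAbundances(m, 1, 6, seed = 9)
  expect_identical(a2, a3)
})

test_that("realized CV concentrates at the closed-form log-normal value", {
  m <- generateProteome(nProteins = 400, seed = 21)
  nm <- noiseModel(sigmaTechShotgun = 0.2367)
  a <- sampleReplicateAbundances(m, 1, 50, nm, "shotgun", seed = 4)
  cv <- apply(a, 1, function(v) 100 * sd(v) / mean(v))
  expect_equal(median(cv), 100 * sqrt(exp(0.2367^2) - 1), tolerance = 0.05)
})

test_that("dephosphorylation conserves abundance and raises pI", {
  m <- generateProteome(nProteins = 60, seed = 12)
  d <- dephosphorylate(m)
  expect_true(all(proteoforms(d)$occupancy == 0))
  perParent <- function(x) tapply(proteoforms(x)$base_abundance,
                                  proteoforms(x)$accession, sum)
  expect_equal(perParent(d)[names(perParent(m))], perParent(m),
               tolerance = 1e-9)
  # idempotence
  expect_identical(proteoforms(dephosphorylate(d)), proteoforms(d))
  # fixed point without phosphorylation
  m0 <- generateProteome(nProteins = 20, phosphoFraction = 0, seed = 8)
  expect_identical(proteoforms(dephosphorylate(m0)), proteoforms(m0))
  # the receiving unmodified form always sits at a pI >= the phospho form's
  pf <- proteoforms(m)
  phos <- pf[pf$n_phospho > 0L, ]
  unmodPi <- ProteoformSim:::.formPhysChem(phos$sequence,
                                           rep(0L, nrow(phos)))$pi
  expect_true(all(unmodPi >= phos$pi))
})

test_that("partial-efficiency treatment scales occupancies", {
  m <- generateProteome(nProteins = 30, seed = 14)
  d <- dephosphorylate(m, efficiency = 0.6)
  pf <- proteoforms(m); pfd <- proteoforms(d)
  phos <- pf$n_phospho > 0L
  expect_equal(pfd$occupancy[phos], pf$occupancy[phos] * 0.4)
  expect_identical(nrow(pfd), nrow(pf))  # nothing merged yet
})

test_that("a model round-trips through its TSV serialization", {
  m <- generateProteome(nProteins = 15, seed = 44)
  dir <- tempfile("model")
  writeProteomeModel(m, dir)
  m2 <- readProteomeModel(dir)
  expect_equal(proteoforms(m2)$base_abundance,
               proteoforms(m)$base_abundance, tolerance = 1e-12)
  expect_identical(proteins(m2), proteins(m))
  expect_equal(m2@config$seed, m@config$seed)
  unlink(dir, recursive = TRUE)
})
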