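# hand-built proteome models and independent oracles shared across tests

# a ProteomeModel from explicit component tables (bypasses the generator)
makeModel <- function(proteins, proteoforms, modifications = NULL) {
  if (is.null(modifications))
    modifications <- data.frame(proteoform_id = character(), site = integer(),
                                mod = character(), occupancy = numeric(),
                                stringsAsFactors = FALSE)
  pc <- ProteoformSim:::.formPhysChem(proteoforms$sequence,
                                      proteoforms$n_phospho)
  proteoforms$pi <- pc$pi
  proteoforms$mw_kda <- pc$mw_kda
  methods::new("ProteomeModel", proteins = proteins,
               proteoforms = proteoforms, modifications = modifications,
               config = list(seed = NA))
}

# one proteoform row with defaults filled in
formRow <- function(id, acc, sequence, start = 1L, end = nchar(sequence),
                    type = "canonical", nPhospho = 0L, occupancy = 0,
                    abundance = 100) {
  data.frame(proteoform_id = id, accession = acc, start = start, end = end,
             sequence = sequence, form_type = type, n_phospho = nPhospho,
             occupancy = occupancy, base_abundance = abundance,
             stringsAsFactors = FALSE)
}

randomSequence <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), n, replace = TRUE),
        collapse = "")
}

# grid-search oracle for the isoelectric point: coarse bracket on [0, 14],
# then a fine local grid -- independent of the bisection under test
gridSearchPI <- function(sequence, mods = NULL, fine = 1e-4) {
  coarse <- seq(0, 14, by = 0.01)
  q <- netCharge(sequence, mods, coarse)
  i <- which.min(abs(q))
  lo <- max(0, coarse[i] - 0.02); hi <- min(14, coarse[i] + 0.02)
  grid <- seq(lo, hi, by = fine)
  grid[which.min(abs(netCharge(sequence, mods, grid)))]
}

# exhaustive digestion oracle: enumerate cleavage junctions by the stated
# trypsin rule and build peptides directly
bruteTrypsin0 <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  sites <- which(chars %in% c("K", "R") & seq_along(chars) < n &
                   c(chars[-1L], "") != "P")
  bounds <- c(0L, sites, n)
  vapply(seq_len(length(bounds) - 1L), function(i)
    substr(sequence, bounds[i] + 1L, bounds[i + 1L]), character(1L))
}

# brute-force Spearman: Pearson on hand-computed midranks
bruteSpearman <- function(x, y) {
  midrank <- function(v) {
    sapply(seq_along(v), function(i)
      sum(v < v[i]) + (1 + sum(v == v[i])) / 2)
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# zero-noise measurement settings: no stochastic loss, no extra noise
noiselessModel <- function(...) {
  noiseModel(sigmaTechDige = 0, sigmaTechShotgun = 0, sigmaBioDige = 0,
             sigmaBioShotgun = 0, sigmaPeptide = 0, sigmaIonization = 0,
             detection = list(digeFloor = 1, digeCeiling = 1,
                              ph69Penalty = 1, shotgunFloor = 1,
                              shotgunCeiling = 1), ...)
}
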