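#' Residue chemistry tables
#'
#' Loads the residue-level physico-chemical constants used throughout the
#' package: average and monoisotopic residue masses, the Bjellqvist pKa set
#' for the ionizable groups relevant on immobilised-pH-gradient gels, and
#' mass/charge deltas for the modelled modifications.  The tables are shipped
#' as plain-text TSV files under \code{inst/extdata} so that they are
#' auditable and swappable.
#'
#' Phosphorylation is modelled as a +79.98 Da (average-mass scale) delta that
#' adds one two-stage acidic group with pKa values 1.2 and 6.5, the standard
#' treatment for phosphomonoesters in gel-era pI estimation.
#'
#' @param path Directory holding \code{residue_masses.tsv},
#'   \code{ionizable_groups.tsv} and \code{modification_deltas.tsv};
#'   defaults to the copies installed with the package.
#' @return A list of class \code{ResidueChemistry} with elements
#'   \code{residue_masses} (named numeric vectors \code{avg} and
#'   \code{mono}), \code{water_mass}, \code{ionizable_groups} (data.frame)
#'   and \code{modification_deltas} (data.frame).
#' @examples
#' chem <- residueChemistry()
#' chem$residue_masses$avg[["G"]]
#' @export
residueChemistry <- function(path = system.file("extdata", package = "ProteoformSim")) {
  masses <- utils::read.delim(file.path(path, "residue_masses.tsv"),
                              stringsAsFactors = FALSE)
  groups <- utils::read.delim(file.path(path, "ionizable_groups.tsv"),
                              stringsAsFactors = FALSE)
  mods <- utils::read.delim(file.path(path, "modification_deltas.tsv"),
                            stringsAsFactors = FALSE)
  stopifnot(all(masses$avg_mass > 0), all(masses$mono_mass > 0),
            all(groups$pka > 0 & groups$pka < 14))
  chem <- list(
    residue_masses = list(avg = stats::setNames(masses$avg_mass, masses$residue),
                          mono = stats::setNames(masses$mono_mass, masses$residue)),
    water_mass = c(avg = 18.0153, mono = 18.010565),
    ionizable_groups = groups,
    modification_deltas = mods)
  class(chem) <- "ResidueChemistry"
  chem
}

# cached chemistry so hot loops do not re-read the TSVs
.chemEnv <- new.env(parent = emptyenv())

.chem <- function() {
  if (is.null(.chemEnv$chem)) .chemEnv$chem <- residueChemistry()
  .chemEnv$chem
}

.checkSequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("'sequence' must be a single non-empty residue string")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(chars, names(.chem()$residue_masses$avg))
  if (length(bad))
    stop("invalid sequence: unknown residue(s) ", paste(unique(bad), collapse = ", "))
  chars
}

.checkMods <- function(mods, n) {
  if (is.null(mods) || length(mods) == 0L)
    return(data.frame(site = integer(), mod = character()))
  if (is.data.frame(mods)) {
    stopifnot(all(c("site", "mod") %in% names(mods)))
  } else stop("'mods' must be NULL or a data.frame with columns site, mod")
  known <- .chem()$modification_deltas$modification
  bad <- setdiff(mods$mod, known)
  if (length(bad)) stop("unknown modification(s): ", paste(bad, collapse = ", "))
  if (any(mods$site < 1L | mods$site > n))
    stop("modification placement error: site index out of range 1..", n)
  mods
}

#' Molecular weight of a (modified) protein or peptide
#'
#' Standard residue-mass summation: the sum of residue masses plus one water,
#' plus the mass deltas of any placed modifications.
#'
#' @param sequence Single-letter residue string (20-letter alphabet).
#' @param mods Optional data.frame with columns \code{site} (1-based residue
#'   index) and \code{mod} (modification name, e.g. \code{"phospho"}).
#' @param scale \code{"avg"} (default; the scale relevant for gel molecular
#'   weights) or \code{"mono"}.
#' @return Mass in Da.
#' @examples
#' molecularWeight("G")   # 75.07
#' molecularWeight("GG")  # 132.12
#' @export
molecularWeight <- function(sequence, mods = NULL, scale = c("avg", "mono")) {
  scale <- match.arg(scale)
  chars <- .checkSequence(sequence)
  mods <- .checkMods(mods, length(chars))
  chem <- .chem()
  mass <- sum(chem$residue_masses[[scale]][chars]) + chem$water_mass[[scale]]
  if (nrow(mods)) {
    deltaCol <- if (scale == "avg") "avg_delta" else "mono_delta"
    idx <- match(mods$mod, chem$modification_deltas$modification)
    mass <- mass + sum(chem$modification_deltas[[deltaCol]][idx])
  }
  unname(mass)
}

# residue/group counts used by the vectorized charge machinery.
# Returns a matrix with one row per sequence and one column per ionizable
# group (D, E, C, Y, H, K, R) plus nphospho.
.ionizableCounts <- function(sequences, nPhospho = rep(0L, length(sequences))) {
  groups <- c("D", "E", "C", "Y", "H", "K", "R")
  counts <- vapply(groups, function(g) {
    nchar(sequences) - nchar(gsub(g, "", sequences, fixed = TRUE))
  }, numeric(length(sequences)))
  counts <- matrix(counts, nrow = length(sequences),
                   dimnames = list(NULL, groups))
  cbind(counts, nphospho = nPhospho)
}

# Henderson-Hasselbalch net charge for count matrices at a vector of pH
# (one pH per row).  Central primitive of the pI solver.
.chargeFromCounts <- function(counts, pH) {
  g <- .chem()$ionizable_groups
  pka <- stats::setNames(g$pka, g$group)
  pos <- 1 / (1 + 10^(pH - pka[["nterm"]])) +
    counts[, "H"] / (1 + 10^(pH - pka[["H"]])) +
    counts[, "K"] / (1 + 10^(pH - pka[["K"]])) +
    counts[, "R"] / (1 + 10^(pH - pka[["R"]]))
  neg <- 1 / (1 + 10^(pka[["cterm"]] - pH)) +
    counts[, "D"] / (1 + 10^(pka[["D"]] - pH)) +
    counts[, "E"] / (1 + 10^(pka[["E"]] - pH)) +
    counts[, "C"] / (1 + 10^(pka[["C"]] - pH)) +
    counts[, "Y"] / (1 + 10^(pka[["Y"]] - pH)) +
    counts[, "nphospho"] * (1 / (1 + 10^(pka[["phospho1"]] - pH)) +
                              1 / (1 + 10^(pka[["phospho2"]] - pH)))
  pos - neg
}

#' Net charge of a peptide or protein at a given pH
#'
#' Henderson--Hasselbalch summation over the ionizable groups (free N- and
#' C-terminus, D, E, C, Y, H, K, R side chains, and any phospho groups, the
#' latter counted as two-stage acids).  Strictly decreasing in pH.
#'
#' @inheritParams molecularWeight
#' @param pH pH value(s) in \eqn{[0, 14]}.
#' @return Signed net charge in elementary charges (vector along \code{pH}).
#' @export
netCharge <- function(sequence, mods = NULL, pH) {
  chars <- .checkSequence(sequence)
  mods <- .checkMods(mods, length(chars))
  if (any(pH < 0 | pH > 14)) stop("pH must lie in [0, 14]")
  counts <- .ionizableCounts(sequence, sum(mods$mod == "phospho"))
  vapply(pH, function(p) .chargeFromCounts(counts, p), numeric(1L))
}

# vectorized bisection on the monotone charge curve; converges until every
# charge is within tol (with margin below the documented 1e-4 contract)
.piFromCounts <- function(counts, tol = 1e-8, maxit = 100L) {
  n <- nrow(counts)
  lo <- rep(0, n); hi <- rep(14, n)
  mid <- (lo + hi) / 2
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    q <- .chargeFromCounts(counts, mid)
    take <- q > 0
    lo[take] <- mid[take]
    hi[!take] <- mid[!take]
    if (all(abs(q) < tol)) break
  }
  mid
}

#' Isoelectric point
#'
#' Finds the pH at which the net charge vanishes, by bisection on
#' \eqn{[0, 14]} (the charge curve is continuous and strictly decreasing, so
#' the root exists and is unique).  Iterates until \eqn{|charge| < 10^{-4}}.
#'
#' Adding a phospho group never increases the pI; removing one never
#' decreases it.
#'
#' @inheritParams molecularWeight
#' @return pI in pH units.
#' @examples
#' isoelectricPoint("KKK") > isoelectricPoint("EEE")
#' @export
isoelectricPoint <- function(sequence, mods = NULL) {
  chars <- .checkSequence(sequence)
  mods <- .checkMods(mods, length(chars))
  counts <- .ionizableCounts(sequence, sum(mods$mod == "phospho"))
  .piFromCounts(counts)
}

#' Proteolytic digestion rules
#'
#' Constructs the cleavage specificity used by \code{\link{digestSequence}}
#' and \code{\link{theoreticalPeptideCount}}.  Presets: \code{"trypsin"}
#' (C-terminal of K/R, not before P), \code{"lysc"} (C-terminal of K), and
#' \code{"trypsin_lysc"} (the mix: K always cleaved, R not before P).
#' The length bounds define which peptides count as "theoretically
#' measurable" for iBAQ; the 6--30 residue default is the common convention.
#'
#' @param protease Preset name.
#' @param maxMissed Maximum missed cleavages reported by
#'   \code{\link{digestSequence}}.
#' @param lengthBounds Integer vector \code{c(min, max)} of measurable
#'   peptide lengths.
#' @return A \code{DigestRule} object.
#' @export
digestRule <- function(protease = c("trypsin", "lysc", "trypsin_lysc"),
                       maxMissed = 0L, lengthBounds = c(6L, 30L)) {
  protease <- match.arg(protease)
  spec <- switch(protease,
    trypsin = list(cleaveAfter = c("K", "R"), blockNext = "P",
                   blockApplies = c("K", "R")),
    lysc = list(cleaveAfter = "K", blockNext = character(),
                blockApplies = character()),
    trypsin_lysc = list(cleaveAfter = c("K", "R"), blockNext = "P",
                        blockApplies = "R"))
  new("DigestRule", protease = protease, cleaveAfter = spec$cleaveAfter,
      blockNext = spec$blockNext, blockApplies = spec$blockApplies,
      maxMissed = as.integer(maxMissed),
      lengthBounds = as.integer(lengthBounds))
}

# perl regex that marks cleavage junctions for a rule
.cleavageRegex <- function(rule) {
  parts <- vapply(rule@cleaveAfter, function(res) {
    if (res %in% rule@blockApplies && length(rule@blockNext))
      sprintf("(?<=%s)(?!(%s|$))", res,
              paste(rule@blockNext, collapse = "|"))
    else sprintf("(?<=%s)(?!$)", res)
  }, character(1L))
  paste(parts, collapse = "|")
}

# fully-cleaved peptides for a character vector of sequences (fast path)
.cleaveMany <- function(sequences, rule) {
  strsplit(gsub(.cleavageRegex(rule), "\x01", sequences, perl = TRUE),
           "\x01", fixed = TRUE)
}

#' In-silico proteolytic digestion
#'
#' Splits a sequence at every cleavage junction of the rule and enumerates
#' all peptides spanning up to \code{rule@maxMissed} internal cleavage sites.
#' The 0-missed-cleavage peptides concatenate to exactly the input sequence.
#'
#' @inheritParams molecularWeight
#' @param rule A \code{\link{digestRule}}.
#' @return data.frame with columns \code{peptide}, \code{start}, \code{end},
#'   \code{missed}.
#' @examples
#' digestSequence("AKRPCKR", digestRule("trypsin"))$peptide
#' @export
digestSequence <- function(sequence, rule = digestRule()) {
  .checkSequence(sequence)
  pieces <- .cleaveMany(sequence, rule)[[1L]]
  ends <- cumsum(nchar(pieces))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- list(data.frame(peptide = pieces, start = starts, end = ends,
                         missed = 0L, stringsAsFactors = FALSE))
  if (rule@maxMissed > 0L && length(pieces) > 1L) {
    for (m in seq_len(min(rule@maxMissed, length(pieces) - 1L))) {
      i <- seq_len(length(pieces) - m)
      pep <- vapply(i, function(k) paste(pieces[k:(k + m)], collapse = ""),
                    character(1L))
      out[[m + 1L]] <- data.frame(peptide = pep, start = starts[i],
                                  end = ends[i + m], missed = m,
                                  stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Number of theoretically measurable peptides (iBAQ denominator)
#'
#' Counts the fully-cleaved (0 missed cleavages) peptides whose length lies
#' within the rule's measurable bounds.  This is the denominator of the iBAQ
#' quantity: summed peptide intensities divided by the number of
#' theoretically measurable tryptic peptides.
#'
#' @inheritParams digestSequence
#' @return Integer count.
#' @export
theoreticalPeptideCount <- function(sequence, rule = digestRule()) {
  .checkSequence(sequence)
  len <- nchar(.cleaveMany(sequence, rule)[[1L]])
  sum(len >= rule@lengthBounds[1L] & len <= rule@lengthBounds[2L])
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over \code{Biostrings::readAAStringSet} returning the plain
#' accession/sequence data.frame the simulators consume.  Accessions are the
#' first whitespace-delimited token of each header.
#'
#' @param path Path to a (possibly line-wrapped, multi-record) FASTA file.
#' @return data.frame with columns \code{accession}, \code{sequence}.
#' @export
readProteinFasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  data.frame(accession = sub("\\s.*$", "", names(aa)),
             sequence = as.character(aa),
             stringsAsFactors = FALSE, row.names = NULL)
}
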