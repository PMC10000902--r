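#' @import methods
NULL

#' DigestRule class
#'
#' Cleavage specificity of a protease plus the length bounds that define
#' "theoretically measurable" peptides.  Build with \code{\link{digestRule}}.
#'
#' @slot protease Preset name.
#' @slot cleaveAfter Residues cleaved C-terminally.
#' @slot blockNext Residues that block cleavage when they follow the site.
#' @slot blockApplies Subset of \code{cleaveAfter} the block applies to.
#' @slot maxMissed Maximum missed cleavages enumerated.
#' @slot lengthBounds \code{c(min, max)} measurable peptide length.
#' @export
setClass("DigestRule",
  representation(protease = "character", cleaveAfter = "character",
                 blockNext = "character", blockApplies = "character",
                 maxMissed = "integer", lengthBounds = "integer"),
  validity = function(object) {
    if (object@maxMissed < 0L) return("maxMissed must be >= 0")
    if (length(object@lengthBounds) != 2L) return("lengthBounds must be c(min, max)")
    if (object@lengthBounds[1L] < 1L) return("min peptide length must be >= 1")
    if (object@lengthBounds[2L] < object@lengthBounds[1L])
      return("max peptide length must be >= min")
    TRUE
  })

setMethod("show", "DigestRule", function(object) {
  cat("DigestRule:", object@protease,
      sprintf("(<=%d missed cleavages, measurable %d-%d aa)\n",
              object@maxMissed, object@lengthBounds[1L], object@lengthBounds[2L]))
})

#' ProteomeModel class
#'
#' Ground-truth container for a synthetic proteoform-resolved proteome:
#' canonical proteins, their proteoforms (possibly truncated and/or
#' phosphorylated, each with a derived pI and molecular weight and a true
#' base abundance in arbitrary volume units), and an echo of the generator
#' configuration including the seed.
#'
#' @slot proteins data.frame(accession, sequence).
#' @slot proteoforms data.frame(proteoform_id, accession, start, end,
#'   sequence, form_type, n_phospho, occupancy, pi, mw_kda, base_abundance).
#' @slot modifications data.frame(proteoform_id, site, mod, occupancy);
#'   site indices are relative to the proteoform sequence.
#' @slot config Generator configuration echo (list; includes \code{seed}).
#' @export
setClass("ProteomeModel",
  representation(proteins = "data.frame", proteoforms = "data.frame",
                 modifications = "data.frame", config = "list"),
  validity = function(object) {
    pf <- object@proteoforms
    pr <- object@proteins
    if (!all(pf$accession %in% pr$accession))
      return("every proteoform must have a parent among the canonical proteins")
    if (!all(pr$accession %in% pf$accession))
      return("each canonical protein must have at least one proteoform")
    if (any(pf$occupancy < 0 | pf$occupancy > 1))
      return("occupancy must lie in [0, 1]")
    if (any(pf$pi <= 0 | pf$pi >= 14)) return("pI must lie in (0, 14)")
    if (any(pf$mw_kda <= 0)) return("MW must be positive")
    if (any(pf$base_abundance <= 0)) return("base abundances must be positive")
    parentLen <- nchar(pr$sequence)[match(pf$accession, pr$accession)]
    if (any(pf$start < 1L | pf$end > parentLen | pf$start > pf$end))
      return("truncations must be contiguous subsequences of the parent")
    TRUE
  })

setMethod("show", "ProteomeModel", function(object) {
  pf <- object@proteoforms
  cat("ProteomeModel:", nrow(object@proteins), "canonical proteins,",
      nrow(pf), "proteoforms\n")
  cat("  forms/protein:", sprintf("%.2f", nrow(pf) / nrow(object@proteins)),
      " phospho forms:", sum(pf$n_phospho > 0),
      " cleavage forms:", sum(pf$form_type == "cleavage"), "\n")
  cat("  abundance range: ",
      sprintf("%.3g-%.3g", min(pf$base_abundance), max(pf$base_abundance)),
      " volume units\n", sep = "")
})

#' @describeIn ProteomeModel-class canonical protein table
#' @param object,x A \code{ProteomeModel}.
#' @export
proteins <- function(x) x@proteins

#' @describeIn ProteomeModel-class proteoform table
#' @export
proteoforms <- function(x) x@proteoforms

#' @describeIn ProteomeModel-class proteoform-level modification table
#' @export
modifications <- function(x) x@modifications

#' @describeIn ProteomeModel-class number of canonical proteins
#' @export
nProteins <- function(x) nrow(x@proteins)

#' @describeIn ProteomeModel-class number of proteoforms
#' @export
nProteoforms <- function(x) nrow(x@proteoforms)

#' NoiseModel class
#'
#' Calibration container for the multiplicative (natural-log-scale) noise
#' and detection behaviour of the two measurement platforms.  Build with
#' \code{\link{noiseModel}}.
#'
#' @slot sigmaTechDige Log-scale sd of 2D-DIGE technical noise on
#'   standardized abundances.
#' @slot sigmaTechShotgun Log-scale sd of shotgun run-to-run technical noise
#'   (protein-level).
#' @slot sigmaBioDige,sigmaBioShotgun Log-scale sd of biological variation
#'   seen by each platform.
#' @slot detection Named list of detection-curve parameters (logistic in log
#'   signal): \code{digeMid}, \code{digeScale}, \code{digeFloor},
#'   \code{digeCeiling}, \code{ph69Penalty}, \code{shotgunMid},
#'   \code{shotgunScale}, \code{shotgunFloor}, \code{shotgunCeiling}.
#' @slot sigmaPeptide Extra per-peptide, per-run log-scale noise in shotgun.
#' @slot sigmaIonization Log-scale sd of the fixed per-peptide ionization
#'   efficiency factor.
#' @slot phosphoPenalty Multiplier on the detection probability of
#'   phosphopeptides in direct (enrichment-free) shotgun.
#' @export
setClass("NoiseModel",
  representation(sigmaTechDige = "numeric", sigmaTechShotgun = "numeric",
                 sigmaBioDige = "numeric", sigmaBioShotgun = "numeric",
                 detection = "list", sigmaPeptide = "numeric",
                 sigmaIonization = "numeric", phosphoPenalty = "numeric"),
  validity = function(object) {
    s <- c(object@sigmaTechDige, object@sigmaTechShotgun, object@sigmaBioDige,
           object@sigmaBioShotgun, object@sigmaPeptide, object@sigmaIonization)
    if (any(s < 0)) return("all sigmas must be >= 0")
    p <- unlist(object@detection[c("digeFloor", "digeCeiling", "ph69Penalty",
                                   "shotgunFloor", "shotgunCeiling")])
    if (any(p < 0 | p > 1)) return("detection probabilities must lie in [0, 1]")
    if (object@phosphoPenalty < 0 || object@phosphoPenalty > 1)
      return("phosphoPenalty must lie in [0, 1]")
    TRUE
  })

setMethod("show", "NoiseModel", function(object) {
  cat("NoiseModel\n")
  cat(sprintf("  sigma_tech: DIGE %.4f (CV ~%.1f%%), shotgun %.4f (CV ~%.1f%%)\n",
              object@sigmaTechDige, 100 * sqrt(exp(object@sigmaTechDige^2) - 1),
              object@sigmaTechShotgun,
              100 * sqrt(exp(object@sigmaTechShotgun^2) - 1)))
  cat(sprintf("  sigma_bio:  DIGE %.4f, shotgun %.4f\n",
              object@sigmaBioDige, object@sigmaBioShotgun))
  cat(sprintf("  phospho detection penalty: %.3g\n", object@phosphoPenalty))
})

#' GelDesign class
#'
#' Layout of a 2D-DIGE experiment: the pH ranges run for every replicate,
#' the gel/channel-to-sample assignments with the Cy2 internal standard on
#' every gel, and the finite (pI, MW) resolution of the gel.  Build with
#' \code{\link{gelDesign}}.
#'
#' @slot phRanges List of numeric \code{c(lower, upper)} pH ranges.
#' @slot gels data.frame(gel_id, channel, sample) with one \code{"IS"}
#'   sample per gel on the internal-standard channel.
#' @slot isChannel Channel name reserved for the internal standard.
#' @slot deltaPi Merge/match tolerance in pH units.
#' @slot deltaMwRel Merge/match tolerance as relative MW difference.
#' @export
setClass("GelDesign",
  representation(phRanges = "list", gels = "data.frame",
                 isChannel = "character", deltaPi = "numeric",
                 deltaMwRel = "numeric"),
  validity = function(object) {
    for (r in object@phRanges)
      if (length(r) != 2L || r[1L] >= r[2L])
        return("each pH range must be c(lower, upper) with lower < upper")
    g <- object@gels
    nIS <- tapply(g$sample == "IS" & g$channel == object@isChannel,
                  g$gel_id, sum)
    if (any(nIS != 1L))
      return("every gel must carry exactly one internal-standard channel")
    if (object@deltaPi <= 0 || object@deltaMwRel <= 0)
      return("resolution tolerances must be positive")
    TRUE
  })

setMethod("show", "GelDesign", function(object) {
  cat("GelDesign:", length(unique(object@gels$gel_id)), "gel(s) x",
      length(object@phRanges), "pH range(s);",
      sum(object@gels$sample != "IS"), "sample channels + IS on",
      object@isChannel, "\n")
  cat(sprintf("  resolution: delta_pI %.3g, delta_MW %.3g%% (relative)\n",
              object@deltaPi, 100 * object@deltaMwRel))
})

#' Remove phosphate groups from a proteome model (lambda-phosphatase)
#'
#' @param model A \code{\link{ProteomeModel-class}} object.
#' @param ... Method arguments, e.g. \code{efficiency}.
#' @export
setGeneric("dephosphorylate", function(model, ...)
  standardGeneric("dephosphorylate"))
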