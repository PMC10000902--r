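#' Classify phosphoproteoform spots from a phosphatase contrast
#'
#' The gel-side phosphoproteoform caller: a spot whose untreated/treated
#' volume ratio strictly exceeds the threshold (default 1.5) is flagged as
#' potentially phosphorylated.  A spot whose treated volume falls below the
#' detection floor while its untreated volume is above it cannot yield a
#' finite ratio and is flagged through the "fully shifted" branch instead
#' of a division.  In the noise-free, full-efficiency limit the expected
#' ratio at a phospho spot with occupancy \eqn{o} is \eqn{1/(1-o)}, so
#' spots with \eqn{o > 1/3} are flagged at the default threshold.
#'
#' @param pairs data.frame from \code{\link{simulatePpaseContrast}} (or any
#'   table with \code{spot_id}, \code{vol_untreated}, \code{vol_treated}).
#' @param threshold Ratio threshold; the comparison is strict (\code{>}).
#' @param detectionFloor Volume below which a spot is considered
#'   undetectable.
#' @return data.frame of class \code{PhosphoCall}: \code{spot_id},
#'   \code{vol_untreated}, \code{vol_treated}, \code{ratio},
#'   \code{threshold}, \code{flagged}, \code{shift_class} (\code{"none"},
#'   \code{"partial"} or \code{"fully_shifted"}), plus any ground-truth
#'   columns carried through.
#' @export
ppaseRatioClassify <- function(pairs, threshold = 1.5, detectionFloor = 0) {
  stopifnot(all(c("spot_id", "vol_untreated", "vol_treated") %in% names(pairs)))
  out <- pairs
  detectable <- out$vol_untreated > detectionFloor
  treatedGone <- out$vol_treated <= detectionFloor
  out$ratio <- ifelse(treatedGone, Inf,
                      out$vol_untreated / out$vol_treated)
  out$threshold <- threshold
  out$flagged <- detectable & (
    (treatedGone & out$vol_untreated > detectionFloor) |
      (!treatedGone & out$ratio > threshold))
  out$shift_class <- ifelse(!out$flagged, "none",
                            ifelse(treatedGone, "fully_shifted", "partial"))
  # untreated-undetectable positions carry no call
  out <- out[detectable, , drop = FALSE]
  class(out) <- c("PhosphoCall", "data.frame")
  out
}

#' Fraction of spots called phosphorylated
#'
#' Headline figure of the phosphatase screen: flagged spots over all
#' 100%-matched spots, as a percentage, rounded half-up to an integer for
#' reporting (the unrounded value is returned alongside).
#'
#' @param flagged Number of flagged spots.
#' @param total Total number of spots considered (> 0).
#' @return List with \code{percent} (integer, half-up) and \code{unrounded}.
#' @examples
#' phosphoFraction(81, 1923)  # 4 (unrounded 4.21)
#' @export
phosphoFraction <- function(flagged, total) {
  if (total <= 0) stop("invalid input: total must be > 0")
  if (flagged < 0 || flagged > total)
    stop("invalid input: flagged must lie in [0, total]")
  p <- 100 * flagged / total
  list(percent = floor(p + 0.5), unrounded = p)
}

#' Stoichiometry from a phospho / dephospho spot pair
#'
#' Plain ratio of the phosphorylated proteoform's spot volume to the
#' unphosphorylated one's -- the quantity the gel platform reads off
#' directly and the peptide-centric platform cannot.  When one side is
#' missing the case is labelled one-sided instead of producing a ratio.
#'
#' @param phosphoVolume,dephosphoVolume Spot volumes (NA = not detected).
#' @return List with \code{ratio} (NA for one-sided cases) and \code{label}
#'   (\code{"two-sided"}, \code{"phospho-only"}, \code{"dephospho-only"} or
#'   \code{"none"}).
#' @examples
#' spotPairStoichiometry(2.7, 1.0)$ratio  # 2.7
#' @export
spotPairStoichiometry <- function(phosphoVolume, dephosphoVolume) {
  hasP <- !is.na(phosphoVolume) && phosphoVolume > 0
  hasD <- !is.na(dephosphoVolume) && dephosphoVolume > 0
  if (hasP && hasD)
    list(ratio = phosphoVolume / dephosphoVolume, label = "two-sided")
  else if (hasP) list(ratio = NA_real_, label = "phospho-only")
  else if (hasD) list(ratio = NA_real_, label = "dephospho-only")
  else list(ratio = NA_real_, label = "none")
}

#' Phosphopeptide-intensity to iBAQ ratios
#'
#' Relates each phosphopeptide's intensity to its parent protein's iBAQ
#' (the per-peptide expectation of the protein's intensity).  Most ratios
#' fall below 1 when phosphorylation stoichiometry is low, since the
#' phosphopeptide carries only the phosphorylated fraction of one peptide's
#' worth of signal.  Records with missing iBAQ are skipped with a logged
#' count.
#'
#' @param phosphoIntensities data.frame with \code{accession} and
#'   \code{intensity} (one row per phosphopeptide observation).
#' @param ibaqTable data.frame with \code{accession} and \code{ibaq}.
#' @return List with \code{ratios} (data.frame accession, intensity, ibaq,
#'   ratio), \code{fractionBelow1} and \code{nSkipped}.
#' @export
ibaqPpeptideRatio <- function(phosphoIntensities, ibaqTable) {
  ib <- ibaqTable[!is.na(ibaqTable$ibaq) & ibaqTable$ibaq > 0, , drop = FALSE]
  ibv <- tapply(ib$ibaq, ib$accession, mean)
  ok <- phosphoIntensities$accession %in% names(ibv) &
    !is.na(phosphoIntensities$intensity)
  nSkipped <- sum(!ok)
  if (nSkipped) message(nSkipped, " phosphopeptide records without iBAQ skipped")
  d <- phosphoIntensities[ok, , drop = FALSE]
  d$ibaq <- as.vector(ibv[d$accession])
  d$ratio <- d$intensity / d$ibaq
  list(ratios = d, fractionBelow1 = mean(d$ratio < 1), nSkipped = nSkipped)
}
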