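#' Construct a 2D-DIGE experimental design
#'
#' Lays out \code{ceiling(nSamples / 2)} gels with two sample channels (Cy3,
#' Cy5) and the pooled internal standard (IS) on Cy2 of every gel, each gel
#' run over every pH range.  Also carries the finite resolution of the gel:
#' proteoforms closer than \code{deltaPi} pH units *and* \code{deltaMwRel}
#' relative MW cannot be separated and co-migrate into one spot.
#'
#' @param samples Character vector of sample (replicate) names, matching the
#'   column names of the abundance matrix given to
#'   \code{\link{simulateGels}}.
#' @param phRanges List of pH ranges; the defaults mirror the classic
#'   acidic (4--7) and alkaline (6--9) IPG strips.  A spot is assigned to
#'   the first listed range containing its pI, so the ranges act as a
#'   partition and composed counts add without double counting.
#' @param deltaPi,deltaMwRel Resolution/matching tolerances.
#' @return A \code{\link{GelDesign-class}} object.
#' @export
gelDesign <- function(samples, phRanges = list(c(4, 7), c(6, 9)),
                      deltaPi = 0.05, deltaMwRel = 0.02) {
  nGels <- ceiling(length(samples) / 2)
  rows <- list()
  for (g in seq_len(nGels)) {
    sams <- samples[(2 * g - 1):min(2 * g, length(samples))]
    ch <- c("Cy3", "Cy5")[seq_along(sams)]
    rows[[g]] <- data.frame(gel_id = sprintf("gel%d", g),
                            channel = c(ch, "Cy2"),
                            sample = c(sams, "IS"),
                            stringsAsFactors = FALSE)
  }
  new("GelDesign", phRanges = phRanges, gels = do.call(rbind, rows),
      isChannel = "Cy2", deltaPi = deltaPi, deltaMwRel = deltaMwRel)
}

.rangeLabel <- function(r) sprintf("%g-%g", r[1L], r[2L])

# first listed range containing the pI, NA if none
.assignRange <- function(pi, phRanges) {
  lab <- rep(NA_character_, length(pi))
  for (r in rev(phRanges))
    lab[pi >= r[1L] & pi <= r[2L]] <- .rangeLabel(r)
  lab
}

#' Form ground-truth 2D spots from a proteome model
#'
#' Groups proteoforms that the gel cannot separate (pI within
#' \code{deltaPi} and MW within \code{deltaMwRel} relative) into single
#' spots with summed volume, drops proteoforms whose pI falls outside every
#' pH range, and records the contributing proteoform ids per spot as ground
#' truth.
#'
#' @param model A \code{\link{ProteomeModel-class}}.
#' @param design A \code{\link{gelDesign}}.
#' @return data.frame with one row per spot: \code{spot_id},
#'   \code{ph_range}, \code{pi}, \code{mw_kda}, \code{base_volume},
#'   \code{n_proteoforms}, \code{proteoform_ids} (";"-separated),
#'   \code{accession} (main contributor), \code{phospho_share}
#'   (abundance-weighted mean phospho occupancy), \code{is_phospho}.
#' @export
formSpots <- function(model, design) {
  pf <- model@proteoforms
  range <- .assignRange(pf$pi, design@phRanges)
  keep <- !is.na(range)
  pf <- pf[keep, , drop = FALSE]
  range <- range[keep]
  ord <- order(pf$pi)
  pf <- pf[ord, , drop = FALSE]
  range <- range[ord]

  n <- nrow(pf)
  cluster <- integer(n)
  cpi <- numeric(0); cmw <- numeric(0); copen <- integer(0)
  nc <- 0L
  for (i in seq_len(n)) {
    # retire clusters that can no longer match (pI sorted ascending)
    if (length(copen))
      copen <- copen[pf$pi[i] - cpi[copen] < design@deltaPi]
    hit <- 0L
    for (k in copen) {
      if (abs(pf$mw_kda[i] - cmw[k]) / cmw[k] < design@deltaMwRel) {
        hit <- k; break
      }
    }
    if (hit == 0L) {
      nc <- nc + 1L
      cpi[nc] <- pf$pi[i]; cmw[nc] <- pf$mw_kda[i]
      copen <- c(copen, nc)
      hit <- nc
    }
    cluster[i] <- hit
  }

  agg <- function(x, f) as.vector(tapply(x, cluster, f))
  occW <- pf$occupancy * pf$base_abundance
  spots <- data.frame(
    pi = agg(pf$pi, mean),
    mw_kda = agg(pf$mw_kda, mean),
    base_volume = agg(pf$base_abundance, sum),
    n_proteoforms = agg(pf$proteoform_id, length),
    proteoform_ids = as.vector(tapply(pf$proteoform_id, cluster, paste,
                                      collapse = ";")),
    stringsAsFactors = FALSE)
  spots$phospho_share <- as.vector(tapply(occW, cluster, sum)) / spots$base_volume
  spots$is_phospho <- as.vector(tapply(pf$n_phospho > 0L & pf$occupancy > 0,
                                       cluster, any))
  main <- tapply(seq_len(n), cluster, function(ix)
    pf$accession[ix[which.max(pf$base_abundance[ix])]])
  spots$accession <- as.vector(main)
  spots$ph_range <- as.vector(tapply(range, cluster, function(x) x[1L]))
  ordS <- order(spots$pi)
  spots <- spots[ordS, , drop = FALSE]
  spots$spot_id <- sprintf("S%05d", seq_len(nrow(spots)))
  rownames(spots) <- NULL
  spots[, c("spot_id", "ph_range", "pi", "mw_kda", "base_volume",
            "n_proteoforms", "proteoform_ids", "accession", "phospho_share",
            "is_phospho")]
}

# spot x replicate volume matrix from per-proteoform abundances
.spotVolumes <- function(spots, abund) {
  ids <- strsplit(spots$proteoform_ids, ";", fixed = TRUE)
  grp <- rep(seq_len(nrow(spots)), lengths(ids))
  rows <- match(unlist(ids), rownames(abund))
  v <- rowsum(abund[rows, , drop = FALSE], group = grp)
  rownames(v) <- spots$spot_id
  v
}

.detectProb <- function(logSignal, mid, scale, floor, ceiling) {
  floor + (ceiling - floor) * stats::plogis((logSignal - mid) / scale)
}

#' Simulate the gel runs of a 2D-DIGE design
#'
#' For every gel, channel and pH range, produces raw spot volumes (true spot
#' volume x channel gain x optional log-normal channel noise), stochastic
#' detection (Bernoulli with probability logistic in log volume; the
#' alkaline 6--9 range carries a detection penalty, reflecting its greater
#' technical difficulty), positional jitter well below the matching
#' tolerance, and channel-normalized volumes.  The internal-standard channel
#' measures the pooled sample (the row mean of the abundance matrix).
#'
#' @param spots Spot map from \code{\link{formSpots}}.
#' @param abund Proteoform x replicate matrix from
#'   \code{\link{sampleReplicateAbundances}}.
#' @param design A \code{\link{gelDesign}} whose sample names index columns
#'   of \code{abund}.
#' @param noise A \code{\link{noiseModel}} (detection parameters used here).
#' @param seed Integer seed.
#' @param channelSigma Extra log-normal channel noise (default 0: the
#'   platform's technical noise is carried by \code{abund}, keeping the CV
#'   calibration exact).
#' @param gains Optional named per-channel gain multipliers.
#' @param jitterPi,jitterMwRel Positional jitter (sd).
#' @return data.frame of spot observations: \code{gel_id}, \code{channel},
#'   \code{sample}, \code{ph_range}, \code{spot_id} (ground truth),
#'   \code{pi}, \code{mw_kda}, \code{raw_volume}, \code{norm_volume}.
#' @export
simulateGels <- function(spots, abund, design, noise = noiseModel(),
                         seed = 1L, channelSigma = 0, gains = NULL,
                         jitterPi = 0.008, jitterMwRel = 0.004) {
  gels <- design@gels
  missingSamples <- setdiff(setdiff(gels$sample, "IS"), colnames(abund))
  if (length(missingSamples))
    stop("configuration error: design samples absent from abundance table: ",
         paste(missingSamples, collapse = ", "))
  set.seed(seed)
  vol <- .spotVolumes(spots, abund)
  isVol <- rowMeans(vol)
  det <- noise@detection
  out <- list()
  for (i in seq_len(nrow(gels))) {
    sam <- gels$sample[i]
    v <- if (sam == "IS") isVol else vol[, sam]
    gain <- if (!is.null(gains) && gels$channel[i] %in% names(gains))
      gains[[gels$channel[i]]] else 1
    raw <- v * gain * exp(stats::rnorm(length(v), 0, channelSigma))
    p <- .detectProb(log(raw), det$digeMid, det$digeScale, det$digeFloor,
                     det$digeCeiling)
    p[spots$ph_range == "6-9"] <- p[spots$ph_range == "6-9"] * det$ph69Penalty
    seen <- stats::runif(length(raw)) < p
    obs <- data.frame(
      gel_id = gels$gel_id[i], channel = gels$channel[i], sample = sam,
      ph_range = spots$ph_range[seen], spot_id = spots$spot_id[seen],
      pi = spots$pi[seen] + stats::rnorm(sum(seen), 0, jitterPi),
      mw_kda = spots$mw_kda[seen] * exp(stats::rnorm(sum(seen), 0, jitterMwRel)),
      raw_volume = raw[seen], stringsAsFactors = FALSE)
    # normalization is per physical run, i.e. per (gel, channel, pH range)
    tot <- stats::ave(obs$raw_volume, obs$ph_range, FUN = sum)
    obs$norm_volume <- obs$raw_volume / tot
    out[[i]] <- obs
  }
  do.call(rbind, out)
}

#' Standardized abundance (SA)
#'
#' The DIGE quantity: within each gel, a spot's channel-normalized volume
#' divided by the normalized volume of the same spot in the
#' internal-standard channel of that gel.  SA of the IS channel itself is
#' identically 1; if the IS channel missed the spot, SA is undefined and the
#' spot propagates as missing for that gel.  SA is invariant to any
#' channel-wide gain.
#'
#' @param observations Output of \code{\link{simulateGels}}.
#' @param design The \code{\link{gelDesign}} used.
#' @return The sample-channel observations with an \code{sa} column
#'   (IS-channel rows are dropped; spots without an IS reading get
#'   \code{NA}).
#' @export
standardizeAbundance <- function(observations, design) {
  isObs <- observations[observations$channel == design@isChannel, ,
                        drop = FALSE]
  sampleObs <- observations[observations$channel != design@isChannel, ,
                            drop = FALSE]
  key <- function(d) paste(d$gel_id, d$spot_id)
  isNorm <- stats::setNames(isObs$norm_volume, key(isObs))
  sampleObs$sa <- sampleObs$norm_volume / isNorm[key(sampleObs)]
  sampleObs
}

#' MatchedSpotTable class
#'
#' Result of cross-replicate spot matching: master-spot by replicate
#' matrices of standardized abundance and normalized volume, with explicit
#' \code{NA} for spots a replicate failed to detect, plus the master spot
#' coordinates.  Rows without any \code{NA} form the "100\% matched" subset
#' every downstream statistic is restricted to (no imputation anywhere).
#'
#' @slot sa Numeric matrix (master spots x replicates) of SA values.
#' @slot normVolume Matching matrix of normalized volumes.
#' @slot spots data.frame of master spot coordinates (\code{spot_id} is the
#'   generator's ground-truth id of the master observation, kept for
#'   validation only; matching itself uses only (pI, MW)).
#' @export
setClass("MatchedSpotTable",
  representation(sa = "matrix", normVolume = "matrix", spots = "data.frame"))

setMethod("show", "MatchedSpotTable", function(object) {
  full <- sum(stats::complete.cases(object@sa))
  cat("MatchedSpotTable:", nrow(object@sa), "master spots x",
      ncol(object@sa), "replicates;", full, "spots 100% matched\n")
})

# greedy nearest-neighbour matching of one observation set to master spots
.matchOne <- function(master, obs, deltaPi, deltaMwRel) {
  res <- rep(NA_integer_, nrow(master))
  used <- logical(nrow(obs))
  for (i in seq_len(nrow(master))) {
    dPi <- abs(obs$pi - master$pi[i])
    dMw <- abs(obs$mw_kda - master$mw_kda[i]) / master$mw_kda[i]
    ok <- which(!used & dPi < deltaPi & dMw < deltaMwRel)
    if (length(ok)) {
      d <- (dPi[ok] / deltaPi)^2 + (dMw[ok] / deltaMwRel)^2
      pick <- ok[which.min(d)]
      res[i] <- pick
      used[pick] <- TRUE
    }
  }
  res
}

#' Match spots across replicates
#'
#' DeCyder-style master matching: the first replicate's spot list is the
#' master; every other replicate's observations are matched greedily to the
#' nearest master spot within the (pI, relative MW) tolerance, separately
#' per pH range.  Unmatched master spots are recorded as missing in that
#' replicate; observations of other replicates with no master counterpart
#' are dropped (they can never become 100\% matched).
#'
#' @param saObs Output of \code{\link{standardizeAbundance}} (a replicate is
#'   identified by its \code{sample} value and is the union of its pH-range
#'   runs).
#' @param design The \code{\link{gelDesign}} (tolerances taken from it).
#' @return A \code{\link{MatchedSpotTable-class}}.
#' @export
matchSpots <- function(saObs, design) {
  reps <- unique(saObs$sample)
  if (length(reps) < 2L) stop("need at least 2 replicates to match")
  byRep <- split(saObs, saObs$sample)[reps]
  master <- byRep[[1L]]
  master <- master[order(master$pi), , drop = FALSE]
  sa <- matrix(NA_real_, nrow(master), length(reps),
               dimnames = list(master$spot_id, reps))
  nv <- sa
  sa[, 1L] <- master$sa
  nv[, 1L] <- master$norm_volume
  for (j in seq_along(reps)[-1L]) {
    obs <- byRep[[j]]
    for (rg in unique(master$ph_range)) {
      mi <- which(master$ph_range == rg)
      oi <- which(obs$ph_range == rg)
      hit <- .matchOne(master[mi, , drop = FALSE], obs[oi, , drop = FALSE],
                       design@deltaPi, design@deltaMwRel)
      sa[mi, j] <- obs$sa[oi][hit]
      nv[mi, j] <- obs$norm_volume[oi][hit]
    }
  }
  new("MatchedSpotTable", sa = sa, normVolume = nv,
      spots = master[, c("spot_id", "ph_range", "pi", "mw_kda")])
}

#' Representative spot volume of 100%-matched spots
#'
#' The per-spot mean of the normalized volumes over all replicates,
#' computed only for spots detected in every replicate (missing entries
#' exclude the spot; nothing is imputed).  This is the "spot size" used for
#' cross-platform rank correlations.
#'
#' @param matched A \code{\link{MatchedSpotTable-class}}.
#' @return data.frame with \code{spot_id}, \code{ph_range}, \code{pi},
#'   \code{mw_kda}, \code{spot_size}.
#' @export
reconstructSpotVolume <- function(matched) {
  full <- stats::complete.cases(matched@normVolume)
  out <- matched@spots[full, , drop = FALSE]
  out$spot_size <- rowMeans(matched@normVolume[full, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Simulate a lambda-phosphatase contrast at the spot level
#'
#' Pairs an untreated gel channel with a dephosphorylated one.  Each spot's
#' treated volume keeps the fraction of its material that was not
#' dephosphorylated, \eqn{V (1 - e \bar{o})} where \eqn{\bar{o}} is the
#' spot's abundance-weighted phospho occupancy and \eqn{e} the enzyme
#' efficiency; the removed material re-migrates to the spot position of the
#' corresponding unmodified species (matched within the gel tolerance, or a
#' new treated-only position), so parent-protein totals are conserved
#' exactly.  With full efficiency a fully occupied spot empties completely.
#'
#' @param model A \code{\link{ProteomeModel-class}}.
#' @param design A \code{\link{gelDesign}}.
#' @param noise A \code{\link{noiseModel}}.
#' @param efficiency Dephosphorylation efficiency in [0, 1].
#' @param seed Integer seed.
#' @param channelSigma Log-normal measurement noise on both channels
#'   (default 0 gives the noise-free algebra).
#' @return data.frame per spot position: \code{spot_id}, \code{pi},
#'   \code{mw_kda}, \code{vol_untreated}, \code{vol_treated},
#'   \code{phospho_share}, \code{is_phospho} (ground truth).
#' @export
simulatePpaseContrast <- function(model, design, noise = noiseModel(),
                                  efficiency = 1, seed = 1L,
                                  channelSigma = 0) {
  stopifnot(efficiency >= 0, efficiency <= 1)
  set.seed(seed)
  spots <- formSpots(model, design)
  pf <- model@proteoforms
  untreated <- spots$base_volume
  treated <- untreated * (1 - efficiency * spots$phospho_share)

  # re-migrated material is booked at the dephosphorylated species'
  # coordinates as treated-only positions, so the ratio at every untreated
  # spot position stays the exact occupancy algebra 1/(1 - e * share)
  phos <- pf[pf$n_phospho > 0L & pf$occupancy > 0, , drop = FALSE]
  extra <- list()
  if (nrow(phos)) {
    pc <- .formPhysChem(phos$sequence, rep(0L, nrow(phos)))
    moved <- efficiency * phos$occupancy * phos$base_abundance
    keep <- moved > 0
    if (any(keep))
      extra[[1L]] <- data.frame(pi = pc$pi[keep], mw_kda = pc$mw_kda[keep],
                                vol = moved[keep])
  }
  out <- data.frame(spot_id = spots$spot_id, pi = spots$pi,
                    mw_kda = spots$mw_kda, vol_untreated = untreated,
                    vol_treated = treated,
                    phospho_share = spots$phospho_share,
                    is_phospho = spots$is_phospho, stringsAsFactors = FALSE)
  if (length(extra)) {
    ex <- do.call(rbind, extra)
    ex <- data.frame(spot_id = sprintf("T%05d", seq_len(nrow(ex))),
                     pi = ex$pi, mw_kda = ex$mw_kda, vol_untreated = 0,
                     vol_treated = ex$vol, phospho_share = 0,
                     is_phospho = FALSE, stringsAsFactors = FALSE)
    out <- rbind(out, ex)
  }
  if (channelSigma > 0) {
    out$vol_untreated <- out$vol_untreated *
      exp(stats::rnorm(nrow(out), 0, channelSigma))
    out$vol_treated <- out$vol_treated *
      exp(stats::rnorm(nrow(out), 0, channelSigma))
  }
  out
}

#' Write / read a spot observation table as TSV
#'
#' Fixed-column TSV (\code{gel_id}, \code{channel}, \code{sample},
#' \code{ph_range}, \code{spot_id}, \code{pi}, \code{mw_kda},
#' \code{raw_volume}, \code{norm_volume}, optionally \code{sa}); missing
#' values written as the literal \code{NA}.
#'
#' @param observations Spot observation data.frame.
#' @param path Output TSV path.
#' @return \code{writeSpotTable}: the path, invisibly;
#'   \code{readSpotTable}: the data.frame.
#' @export
writeSpotTable <- function(observations, path) {
  .writeTsv(observations, path)
  invisible(path)
}

#' @rdname writeSpotTable
#' @export
readSpotTable <- function(path) .readTsv(path)
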