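# average human residue frequencies (UniProt human proteome, percent scale)
.humanAAFreq <- c(
  A = 7.0, R = 5.6, N = 3.6, D = 4.7, C = 2.3, Q = 4.8, E = 7.1, G = 6.6,
  H = 2.6, I = 4.3, L = 10.0, K = 5.7, M = 2.1, F = 3.7, P = 6.3, S = 8.3,
  T = 5.4, W = 1.2, Y = 2.7, V = 6.0)

.randomSequences <- function(n, meanLength = 450, sdlogLength = 0.35,
                             minLength = 50L) {
  len <- pmax(minLength,
              round(stats::rlnorm(n, log(meanLength), sdlogLength)))
  aa <- names(.humanAAFreq)
  vapply(len, function(L)
    paste(sample(aa, L, replace = TRUE, prob = .humanAAFreq), collapse = ""),
    character(1L))
}

# pI and MW for a proteoform table (vectorized)
.formPhysChem <- function(sequences, nPhospho) {
  chem <- .chem()
  m <- chem$residue_masses$avg
  mw <- rep(chem$water_mass[["avg"]], length(sequences))
  for (res in names(m))
    mw <- mw + m[[res]] *
      (nchar(sequences) - nchar(gsub(res, "", sequences, fixed = TRUE)))
  phDelta <- chem$modification_deltas$avg_delta[
    chem$modification_deltas$modification == "phospho"]
  mw <- mw + nPhospho * phDelta
  counts <- .ionizableCounts(sequences, nPhospho)
  list(pi = .piFromCounts(counts), mw_kda = mw / 1000)
}

#' Generate a synthetic proteoform-resolved proteome
#'
#' Draws canonical protein sequences from average human residue frequencies
#' (length log-normal around 450 residues), assigns each protein
#' \eqn{1 + Poisson(mean - 1)} proteoforms, and realises the extra forms as
#' either phosphorylation variants (1..\code{maxPhosphoSites} phospho groups
#' on S/T/Y with a fractional site occupancy) or proteolytic cleavage
#' variants (one contiguous fragment after a single cut at a uniformly
#' random internal site, recorded as ground truth).  Base abundances are
#' log-normal over a wide dynamic range (more than three orders of magnitude
#' under the defaults).  All physico-chemical coordinates (pI, MW) are
#' derived from the sequence and modifications.
#'
#' @param nProteins Number of canonical proteins.
#' @param meanProteoforms Mean proteoforms per protein (default 3, the
#'   classic 2D-gel-era estimate for eukaryotes; the proteoform-atlas-scale
#'   alternative of ~17.5 is reachable through this knob).
#' @param phosphoFraction Fraction of the extra (non-canonical) proteoforms
#'   that are phosphorylation variants; the rest are cleavage variants.
#' @param maxPhosphoSites Maximum phospho groups per phospho form.
#' @param occupancyRange Range of the uniform draw of phospho site
#'   occupancy.
#' @param abundanceMeanlog,abundanceSdlog Log-normal parameters of base
#'   abundance (arbitrary volume units; only ratios and ranks matter).
#' @param meanLength,sdlogLength Sequence-length distribution parameters.
#' @param sequences Optional data.frame(accession, sequence) (e.g. from
#'   \code{\link{readProteinFasta}}) to use instead of random sequences.
#' @param seed Integer seed; the model is byte-identical for a fixed seed.
#' @return A \code{\link{ProteomeModel-class}} object.
#' @examples
#' m <- generateProteome(nProteins = 20, seed = 1)
#' nProteins(m); nProteoforms(m)
#' @export
generateProteome <- function(nProteins = 500, meanProteoforms = 3,
                             phosphoFraction = 0.5, maxPhosphoSites = 3L,
                             occupancyRange = c(0.05, 0.95),
                             abundanceMeanlog = log(500), abundanceSdlog = 2,
                             meanLength = 450, sdlogLength = 0.35,
                             sequences = NULL, seed = 1L) {
  if (nProteins < 1 || meanProteoforms < 1)
    stop("configuration error: nProteins and meanProteoforms must be >= 1")
  if (phosphoFraction < 0 || phosphoFraction > 1)
    stop("configuration error: phosphoFraction must lie in [0, 1]")
  set.seed(seed)
  if (is.null(sequences)) {
    proteins <- data.frame(
      accession = sprintf("SYN%05d", seq_len(nProteins)),
      sequence = .randomSequences(nProteins, meanLength, sdlogLength),
      stringsAsFactors = FALSE)
  } else {
    proteins <- sequences[, c("accession", "sequence")]
    nProteins <- nrow(proteins)
  }

  nForms <- 1L + stats::rpois(nProteins, meanProteoforms - 1)
  N <- sum(nForms)
  fid <- acc <- seqv <- type <- character(N)
  s0 <- e0 <- nph <- integer(N)
  occv <- abv <- numeric(N)
  modrows <- vector("list", N)
  styList <- gregexpr("[STY]", proteins$sequence)
  k <- 0L
  for (i in seq_len(nProteins)) {
    seqi <- proteins$sequence[i]; acci <- proteins$accession[i]
    L <- nchar(seqi)
    base <- stats::rlnorm(1L, abundanceMeanlog, abundanceSdlog)
    # canonical (unmodified, full-length) form always present
    k <- k + 1L
    fid[k] <- sprintf("%s.1", acci); acc[k] <- acci; seqv[k] <- seqi
    s0[k] <- 1L; e0[k] <- L; type[k] <- "canonical"; nph[k] <- 0L
    occv[k] <- 0; abv[k] <- base
    if (nForms[i] > 1L) for (j in seq_len(nForms[i] - 1L)) {
      relAbund <- stats::rlnorm(1L, -0.7, 0.8)  # extra forms usually minor
      if (stats::runif(1L) < phosphoFraction) {
        sty <- as.integer(styList[[i]])
        if (sty[1L] == -1L) next  # no phosphorylatable site; skip this form
        np <- min(sample.int(maxPhosphoSites, 1L), length(sty))
        sites <- sort(sty[sample.int(length(sty), np)])
        occ <- stats::runif(1L, occupancyRange[1L], occupancyRange[2L])
        k <- k + 1L
        fid[k] <- sprintf("%s.%d", acci, j + 1L); acc[k] <- acci
        seqv[k] <- seqi; s0[k] <- 1L; e0[k] <- L; type[k] <- "phospho"
        nph[k] <- np; occv[k] <- occ; abv[k] <- base * relAbund
        modrows[[k]] <- data.frame(proteoform_id = fid[k], site = sites,
                                   mod = "phospho", occupancy = occ,
                                   stringsAsFactors = FALSE)
      } else {
        cut <- sample(seq(30L, max(31L, L - 30L)), 1L)
        keepN <- stats::runif(1L) < 0.5
        k <- k + 1L
        fid[k] <- sprintf("%s.%d", acci, j + 1L); acc[k] <- acci
        s0[k] <- if (keepN) 1L else cut + 1L
        e0[k] <- if (keepN) cut else L
        seqv[k] <- substr(seqi, s0[k], e0[k]); type[k] <- "cleavage"
        nph[k] <- 0L; occv[k] <- 0; abv[k] <- base * relAbund
      }
    }
  }
  idx <- seq_len(k)
  pf <- data.frame(proteoform_id = fid[idx], accession = acc[idx],
                   start = s0[idx], end = e0[idx], sequence = seqv[idx],
                   form_type = type[idx], n_phospho = nph[idx],
                   occupancy = occv[idx], base_abundance = abv[idx],
                   stringsAsFactors = FALSE)
  modrows <- modrows[!vapply(modrows, is.null, logical(1L))]
  mods <- if (length(modrows)) do.call(rbind, modrows) else
    data.frame(proteoform_id = character(), site = integer(),
               mod = character(), occupancy = numeric(),
               stringsAsFactors = FALSE)
  pc <- .formPhysChem(pf$sequence, pf$n_phospho)
  pf$pi <- pc$pi
  pf$mw_kda <- pc$mw_kda
  cfg <- list(nProteins = nProteins, meanProteoforms = meanProteoforms,
              phosphoFraction = phosphoFraction,
              maxPhosphoSites = maxPhosphoSites,
              abundanceMeanlog = abundanceMeanlog,
              abundanceSdlog = abundanceSdlog, meanLength = meanLength,
              sdlogLength = sdlogLength, seed = seed)
  new("ProteomeModel", proteins = proteins, proteoforms = pf,
      modifications = mods, config = cfg)
}

#' Default noise model
#'
#' Platform noise calibrated so that the closed-form log-normal CV,
#' \eqn{100\sqrt{e^{\sigma^2} - 1}}, matches the platform-typical values:
#' 2D-DIGE technical CV about 7.6\% (sigma 0.0759), shotgun technical CV
#' about 24\% (sigma 0.2367), and total (technical + biological) CVs of
#' about 13\% and 59\% (combined sigmas 0.1295 and 0.5466, from which the
#' biological components are obtained by variance subtraction).  The
#' phosphopeptide detection penalty reflects direct, enrichment-free
#' acquisition, under which well below 1\% of identified proteins show a
#' phosphopeptide.
#'
#' @param sigmaTechDige,sigmaTechShotgun,sigmaBioDige,sigmaBioShotgun
#'   Log-scale standard deviations of multiplicative noise.
#' @param detection Detection-curve parameters; see
#'   \code{\link{NoiseModel-class}}.
#' @param sigmaPeptide Per-peptide per-run log-scale noise (shotgun).
#' @param sigmaIonization Spread of the fixed per-peptide ionization factor.
#' @param phosphoPenalty Detection-probability multiplier for
#'   phosphopeptides.
#' @return A \code{\link{NoiseModel-class}} object.
#' @export
noiseModel <- function(sigmaTechDige = 0.0759, sigmaTechShotgun = 0.2367,
                       sigmaBioDige = sqrt(0.1295^2 - 0.0759^2),
                       sigmaBioShotgun = sqrt(0.5466^2 - 0.2367^2),
                       detection = list(), sigmaPeptide = 0.05,
                       sigmaIonization = 1, phosphoPenalty = 0.005) {
  det <- list(digeMid = log(5), digeScale = 1.2, digeFloor = 0.005,
              digeCeiling = 0.998, ph69Penalty = 0.9,
              shotgunMid = log(2000), shotgunScale = 1.5, shotgunFloor = 0.01,
              shotgunCeiling = 0.97)
  det[names(detection)] <- detection
  new("NoiseModel", sigmaTechDige = sigmaTechDige,
      sigmaTechShotgun = sigmaTechShotgun, sigmaBioDige = sigmaBioDige,
      sigmaBioShotgun = sigmaBioShotgun, detection = det,
      sigmaPeptide = sigmaPeptide, sigmaIonization = sigmaIonization,
      phosphoPenalty = phosphoPenalty)
}

#' Per-replicate true abundances
#'
#' Realises the replicate structure of the study design: biological
#' replicates draw a shared multiplicative log-normal deviation from the
#' proteoform's base abundance, and the technical replicates within each
#' biological replicate draw independent technical deviations on top.  The
#' technical sigma of the chosen platform is applied here, so that
#' downstream coefficient-of-variation summaries are calibrated directly
#' against the closed form \eqn{CV = \sqrt{e^{\sigma^2} - 1}}.
#'
#' @param model A \code{\link{ProteomeModel-class}}.
#' @param nBio Number of biological replicates (1 = pooled technical-only
#'   design).
#' @param nTechPerBio Technical replicates per biological replicate.
#' @param noise A \code{\link{noiseModel}}.
#' @param method \code{"dige"} or \code{"shotgun"}: selects which technical
#'   and biological sigmas apply.
#' @param seed Integer seed.
#' @return Numeric matrix proteoform x replicate (column names
#'   \code{b<i>_t<j>}), all entries positive, with attributes \code{bio}
#'   (bio index per column) and \code{method}.
#' @export
sampleReplicateAbundances <- function(model, nBio = 1L, nTechPerBio = 6L,
                                      noise = noiseModel(),
                                      method = c("dige", "shotgun"),
                                      seed = 1L) {
  method <- match.arg(method)
  if (nBio < 1L || nTechPerBio < 1L) stop("nBio and nTechPerBio must be >= 1")
  set.seed(seed)
  sTech <- if (method == "dige") noise@sigmaTechDige else noise@sigmaTechShotgun
  sBio <- if (method == "dige") noise@sigmaBioDige else noise@sigmaBioShotgun
  base <- model@proteoforms$base_abundance
  nf <- length(base)
  cols <- list(); bio <- integer()
  for (b in seq_len(nBio)) {
    bioDev <- if (nBio == 1L) rep(0, nf) else stats::rnorm(nf, 0, sBio)
    for (t in seq_len(nTechPerBio)) {
      cols[[length(cols) + 1L]] <- base * exp(bioDev) *
        exp(stats::rnorm(nf, 0, sTech))
      bio <- c(bio, b)
    }
  }
  m <- do.call(cbind, cols)
  dimnames(m) <- list(model@proteoforms$proteoform_id,
                      sprintf("b%d_t%d", bio,
                              stats::ave(bio, bio, FUN = seq_along)))
  attr(m, "bio") <- bio
  attr(m, "method") <- method
  m
}

#' @describeIn dephosphorylate Removes phosphate groups from every phospho
#'   proteoform with the given efficiency: occupancies are scaled by
#'   \code{1 - efficiency} (set to 0 at the default full efficiency), and a
#'   form whose occupancy reaches 0 is chemically identical to the
#'   unmodified form of the same sequence, so it merges into it (abundances
#'   summed; the unmodified form is created if the parent had none).  Total
#'   abundance per parent protein is conserved exactly, and every merged
#'   form moves to a pI at least as high as before (phosphate loss raises
#'   the pI).
#' @param efficiency Fraction of phosphate groups removed, in [0, 1].
#' @export
setMethod("dephosphorylate", "ProteomeModel",
          function(model, efficiency = 1) {
  stopifnot(efficiency >= 0, efficiency <= 1)
  pf <- model@proteoforms
  mods <- model@modifications
  isPhos <- pf$n_phospho > 0L & pf$occupancy > 0
  if (!any(isPhos) || efficiency == 0) return(model)
  pf$occupancy[isPhos] <- pf$occupancy[isPhos] * (1 - efficiency)
  if (nrow(mods)) mods$occupancy <- mods$occupancy * (1 - efficiency)
  done <- pf$n_phospho > 0L & pf$occupancy == 0
  if (any(done)) {
    for (i in which(done)) {
      target <- which(!(pf$n_phospho > 0L & pf$occupancy > 0) & !done &
                        pf$accession == pf$accession[i] &
                        pf$sequence == pf$sequence[i])
      if (length(target)) {
        pf$base_abundance[target[1L]] <-
          pf$base_abundance[target[1L]] + pf$base_abundance[i]
      } else {
        # no unmodified twin: the form itself becomes the unmodified entry
        pf$n_phospho[i] <- 0L
        pf$form_type[i] <- if (pf$start[i] == 1L &&
                               pf$end[i] == nchar(model@proteins$sequence[
                                 match(pf$accession[i],
                                       model@proteins$accession)]))
          "canonical" else "cleavage"
        done[i] <- FALSE
      }
    }
    # recompute coordinates of any re-typed forms, then drop merged rows
    redo <- pf$n_phospho == 0L & model@proteoforms$n_phospho > 0L & !done
    if (any(redo)) {
      pc <- .formPhysChem(pf$sequence[redo], rep(0L, sum(redo)))
      pf$pi[redo] <- pc$pi
      pf$mw_kda[redo] <- pc$mw_kda
    }
    mods <- mods[!(mods$proteoform_id %in% pf$proteoform_id[done | redo]), ,
                 drop = FALSE]
    pf <- pf[!done, , drop = FALSE]
  }
  rownames(pf) <- NULL
  new("ProteomeModel", proteins = model@proteins, proteoforms = pf,
      modifications = mods,
      config = c(model@config, list(dephosphorylated = TRUE,
                                    efficiency = efficiency)))
})

#' Write / read a proteome model as documented TSV
#'
#' Serialises a model as a TSV pair (\code{proteins.tsv},
#' \code{proteoforms.tsv}) plus \code{modifications.tsv} and a YAML echo of
#' the generator configuration (including the seed).  \code{readProteomeModel}
#' reverses the operation.
#'
#' @param model A \code{\link{ProteomeModel-class}}.
#' @param dir Output directory (created if missing).
#' @return \code{writeProteomeModel}: the directory, invisibly;
#'   \code{readProteomeModel}: the model.
#' @export
writeProteomeModel <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  .writeTsv(model@proteins, file.path(dir, "proteins.tsv"))
  .writeTsv(model@proteoforms, file.path(dir, "proteoforms.tsv"))
  .writeTsv(model@modifications, file.path(dir, "modifications.tsv"))
  yaml::write_yaml(model@config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname writeProteomeModel
#' @export
readProteomeModel <- function(dir) {
  new("ProteomeModel",
      proteins = .readTsv(file.path(dir, "proteins.tsv")),
      proteoforms = .readTsv(file.path(dir, "proteoforms.tsv")),
      modifications = .readTsv(file.path(dir, "modifications.tsv")),
      config = yaml::read_yaml(file.path(dir, "config.yaml")))
}

# TSV conventions: tab-separated, "NA" for missing, UTF-8, LF
.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
}

.readTsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}
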