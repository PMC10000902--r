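#' @importFrom data.table data.table := .N setDT setnames rbindlist
NULL

#' Parameters of the label-free shotgun simulation
#'
#' @param rule Digestion rule (default the trypsin/Lys-C mix with 2 missed
#'   cleavage sites allowed for identification-style enumeration; intensity
#'   book-keeping uses the fully cleaved peptides so that every molecule is
#'   counted exactly once).
#' @param locAlpha,locBeta Beta parameters of the simulated phospho-site
#'   localization confidence.
#' @param pNoIntensity Probability that a detected peptide yields an
#'   identification without a usable intensity (seen in sparse DDA data).
#' @return List of class \code{ShotgunParams}.
#' @export
shotgunParams <- function(rule = digestRule("trypsin_lysc", maxMissed = 2L),
                          locAlpha = 8, locBeta = 2, pNoIntensity = 0.1) {
  structure(list(rule = rule, locAlpha = locAlpha, locBeta = locBeta,
                 pNoIntensity = pNoIntensity), class = "ShotgunParams")
}

# peptide universe of a model: one row per (proteoform, measurable peptide,
# modification state) with its intensity weight
.peptideUniverse <- function(model, rule) {
  pf <- model@proteoforms
  pieces <- .cleaveMany(pf$sequence, rule)
  lens <- lapply(pieces, nchar)
  nPep <- lengths(pieces)
  formIdx <- rep(seq_len(nrow(pf)), nPep)
  dt <- data.table(
    form_idx = formIdx,
    proteoform_id = pf$proteoform_id[formIdx],
    accession = pf$accession[formIdx],
    sequence = unlist(pieces),
    pep_end = unlist(lapply(lens, cumsum)))
  dt[, pep_start := pep_end - nchar(sequence) + 1L]
  dt <- dt[nchar(sequence) >= rule@lengthBounds[1L] &
             nchar(sequence) <= rule@lengthBounds[2L]]

  mods <- model@modifications
  occ <- pf$occupancy
  if (nrow(mods)) {
    mdt <- data.table(proteoform_id = mods$proteoform_id, site = mods$site)
    hasSite <- merge(dt[, .(proteoform_id, sequence, pep_start, pep_end)],
                     mdt, by = "proteoform_id", allow.cartesian = TRUE)
    hasSite <- hasSite[site >= pep_start & site <= pep_end,
                       .(n_sites = .N),
                       by = .(proteoform_id, sequence, pep_start)]
    dt <- merge(dt, hasSite, by = c("proteoform_id", "sequence", "pep_start"),
                all.x = TRUE)
  } else dt[, n_sites := NA_integer_]
  dt[, n_sites := ifelse(is.na(n_sites), 0L, n_sites)]

  unmod <- dt[, .(form_idx, proteoform_id, accession, sequence,
                  mod_state = "none",
                  weight = ifelse(n_sites > 0L, 1 - occ[form_idx], 1))]
  phos <- dt[n_sites > 0L,
             .(form_idx, proteoform_id, accession, sequence,
               mod_state = "phospho", weight = occ[form_idx])]
  rbindlist(list(unmod[weight > 0], phos[weight > 0]))
}

#' Simulate label-free shotgun LC-MS/MS runs
#'
#' Digests every proteoform into the shared peptide pool (the step that
#' deliberately erases proteoform identity), assigns each unique peptide a
#' fixed log-normal ionization efficiency, and for every run draws peptide
#' intensities (summed over all contributing proteoforms, with phospho
#' occupancy splitting a site-bearing peptide into its modified and
#' unmodified states) with per-peptide run noise.  Detection emulates
#' data-dependent acquisition: a Bernoulli draw with probability logistic in
#' log intensity, so low-abundance peptides go stochastically missing;
#' phosphopeptides have their detection probability multiplied by the
#' direct-acquisition penalty.  Detected phosphopeptides receive a simulated
#' localization confidence (Beta distributed).
#'
#' @param model A \code{\link{ProteomeModel-class}}.
#' @param abund Proteoform x run abundance matrix from
#'   \code{\link{sampleReplicateAbundances}} (\code{method = "shotgun"}).
#' @param params A \code{\link{shotgunParams}}.
#' @param noise A \code{\link{noiseModel}}.
#' @param seed Integer seed.
#' @param fullDetection If TRUE, skip the stochastic detection and report
#'   every peptide (the zero-noise/complete-data limit used by identities
#'   and oracles).
#' @return data.frame of peptide observations: \code{run_id},
#'   \code{sequence}, \code{mod_state}, \code{intensity}, \code{quantified},
#'   \code{loc_prob}, \code{accessions} (";"-joined),
#'   \code{proteoform_ids} (ground truth, ";"-joined).
#' @export
simulateShotgunRuns <- function(model, abund, params = shotgunParams(),
                                noise = noiseModel(), seed = 1L,
                                fullDetection = FALSE) {
  set.seed(seed)
  uni <- .peptideUniverse(model, params$rule)
  key <- paste(uni$sequence, uni$mod_state)
  grp <- match(key, unique(key))
  trueI <- rowsum(abund[uni$form_idx, , drop = FALSE] * uni$weight,
                  group = grp)
  meta <- uni[, .(accessions = paste(sort(unique(accession)), collapse = ";"),
                  proteoform_ids = paste(sort(unique(proteoform_id)),
                                         collapse = ";")),
              by = .(g = grp, sequence, mod_state)]
  data.table::setkey(meta, g)
  meta <- meta[.(sort(unique(grp)))]

  ion <- exp(stats::rnorm(nrow(trueI), 0, noise@sigmaIonization))
  det <- noise@detection
  runs <- colnames(abund)
  out <- vector("list", length(runs))
  for (r in seq_along(runs)) {
    I <- trueI[, r] * ion *
      exp(stats::rnorm(nrow(trueI), 0, noise@sigmaPeptide))
    if (fullDetection) {
      seen <- I > 0
    } else {
      p <- .detectProb(log(pmax(I, 1e-300)), det$shotgunMid, det$shotgunScale,
                       det$shotgunFloor, det$shotgunCeiling)
      p[meta$mod_state == "phospho"] <- p[meta$mod_state == "phospho"] *
        noise@phosphoPenalty
      seen <- stats::runif(length(I)) < p
    }
    n <- sum(seen)
    obs <- data.table(run_id = runs[r], sequence = meta$sequence[seen],
                      mod_state = meta$mod_state[seen], intensity = I[seen],
                      accessions = meta$accessions[seen],
                      proteoform_ids = meta$proteoform_ids[seen])
    obs[, quantified := if (fullDetection) TRUE else
      stats::runif(.N) >= params$pNoIntensity]
    obs[, intensity := ifelse(quantified, intensity, NA_real_)]
    obs[, loc_prob := ifelse(mod_state == "phospho",
                             stats::rbeta(.N, params$locAlpha, params$locBeta),
                             NA_real_)]
    out[[r]] <- obs
  }
  as.data.frame(rbindlist(out))
}

#' Infer protein groups from peptide observations
#'
#' Reassembles peptides into canonical-protein groups: every peptide is
#' assigned to one accession (peptides mapping to several accessions go to
#' the accession with more distinct detected peptide sequences, ties broken
#' lexicographically), and all proteoforms of an accession collapse into a
#' single group -- proteoform identity is deliberately not an output.
#'
#' @param peptideObs Output of \code{\link{simulateShotgunRuns}}.
#' @param model Optional \code{\link{ProteomeModel-class}} for the
#'   ground-truth \code{n_proteoforms_collapsed} column.
#' @return data.frame per (accession, run): \code{accession},
#'   \code{run_id}, \code{intensity_sum} (quantified peptides),
#'   \code{n_peptides} (distinct detected sequences),
#'   \code{n_phosphopeptides}, and, with a model,
#'   \code{n_proteoforms_collapsed}.
#' @export
inferProteinGroups <- function(peptideObs, model = NULL) {
  dt <- data.table::as.data.table(peptideObs)
  # evidence-based resolution of shared peptides, pooled over runs
  dt <- merge(dt, .peptideAssignment(peptideObs), by = "sequence")

  groups <- dt[, .(
    intensity_sum = sum(intensity[quantified], na.rm = TRUE),
    n_peptides = data.table::uniqueN(sequence),
    n_phosphopeptides = data.table::uniqueN(sequence[mod_state == "phospho"])),
    by = .(accession, run_id)]
  if (!is.null(model)) {
    nf <- table(model@proteoforms$accession)
    groups[, n_proteoforms_collapsed := as.integer(nf[accession])]
  }
  data.table::setorder(groups, run_id, accession)
  as.data.frame(groups)
}

#' Label-free quantification (LFQ) across runs
#'
#' Simplified label-free protein quantification: each run is first scaled by
#' the median peptide-intensity ratio to a reference run (computed over the
#' peptides the two runs share), then the protein LFQ in a run is the sum of
#' its detected, normalized peptide intensities.  This reproduces the
#' essential properties of MS1-based label-free quantification -- scale
#' invariance across runs and peptide-sum protein intensities -- without the
#' full pairwise least-squares machinery of MaxLFQ.
#'
#' @inheritParams inferProteinGroups
#' @param referenceRun Run id used as scaling reference (default: first).
#' @return data.frame per (accession, run): \code{accession}, \code{run_id},
#'   \code{lfq}; a group with no quantified peptide in a run is absent
#'   (missing, never imputed).
#' @export
computeLfq <- function(peptideObs, referenceRun = NULL) {
  dt <- data.table::as.data.table(peptideObs)[quantified & !is.na(intensity)]
  runs <- unique(dt$run_id)
  if (is.null(referenceRun)) referenceRun <- runs[1L]
  ref <- dt[run_id == referenceRun,
            .(ref_int = sum(intensity)), by = .(sequence, mod_state)]
  factors <- stats::setNames(rep(1, length(runs)), runs)
  for (r in setdiff(runs, referenceRun)) {
    cur <- dt[run_id == r, .(cur_int = sum(intensity)),
              by = .(sequence, mod_state)]
    shared <- merge(ref, cur, by = c("sequence", "mod_state"))
    if (nrow(shared))
      factors[[r]] <- stats::median(shared$ref_int / shared$cur_int)
  }
  dt[, norm_intensity := intensity * factors[run_id]]
  # shared-peptide assignment identical to inferProteinGroups
  dt <- merge(dt, .peptideAssignment(peptideObs), by = "sequence")
  out <- dt[, .(lfq = sum(norm_intensity)), by = .(accession, run_id)]
  data.table::setorder(out, run_id, accession)
  as.data.frame(out)
}

# evidence-maximal peptide -> accession assignment (shared helper)
.peptideAssignment <- function(peptideObs) {
  dt <- data.table::as.data.table(peptideObs)
  cand <- unique(dt[, .(sequence, accessions)])
  cand <- cand[, .(accession = strsplit(accessions, ";", fixed = TRUE)[[1L]]),
               by = sequence]
  evidence <- cand[, .(n_seq = data.table::uniqueN(sequence)), by = accession]
  cand <- merge(cand, evidence, by = "accession")
  data.table::setorder(cand, sequence, -n_seq, accession)
  cand[, .SD[1L], by = sequence][, .(sequence, accession)]
}

#' iBAQ: intensity-based absolute quantification
#'
#' For each protein group, the summed measured peptide intensities divided
#' by the number of theoretically measurable fully-cleaved peptides of the
#' canonical sequence (see \code{\link{theoreticalPeptideCount}}).  Proteins
#' whose sequence yields no measurable peptide have undefined iBAQ and are
#' reported as missing.
#'
#' @inheritParams inferProteinGroups
#' @param model The \code{\link{ProteomeModel-class}} supplying canonical
#'   sequences.
#' @param rule Digestion rule whose length bounds define "measurable".
#' @return data.frame per (accession, run): \code{accession}, \code{run_id},
#'   \code{intensity_sum}, \code{n_theoretical}, \code{ibaq}.
#' @export
computeIbaq <- function(peptideObs, model, rule = digestRule()) {
  dt <- data.table::as.data.table(peptideObs)[quantified & !is.na(intensity)]
  dt <- merge(dt, .peptideAssignment(peptideObs), by = "sequence")
  sums <- dt[, .(intensity_sum = sum(intensity)), by = .(accession, run_id)]
  seqs <- model@proteins
  nTheo <- vapply(seqs$sequence, theoreticalPeptideCount, integer(1L),
                  rule = rule, USE.NAMES = FALSE)
  sums[, n_theoretical := nTheo[match(accession, seqs$accession)]]
  sums[, ibaq := ifelse(n_theoretical >= 1L, intensity_sum / n_theoretical,
                        NA_real_)]
  data.table::setorder(sums, run_id, accession)
  as.data.frame(sums)
}

#' Phosphopeptide accounting across a phosphatase contrast
#'
#' Set-based accounting of phosphopeptides in paired untreated / treated
#' run sets: per condition the detected, localized (localization confidence
#' above the threshold) and quantified (localized with a usable intensity)
#' phosphopeptides and their parent proteins, plus the three-way overlap
#' (untreated-only, both, treated-only) computed exactly on the localized
#' sets.
#'
#' @param untreatedObs,treatedObs Peptide observation tables from
#'   \code{\link{simulateShotgunRuns}}.
#' @param locThreshold Localization-confidence threshold (default 0.75).
#' @return List with per-condition counts (\code{detected},
#'   \code{localized}, \code{quantified}, \code{proteins}) and overlap
#'   counts (\code{only_untreated}, \code{both}, \code{only_treated},
#'   \code{proteins_only_untreated}, \code{proteins_both},
#'   \code{proteins_only_treated}).
#' @export
phosphositeAccounting <- function(untreatedObs, treatedObs,
                                  locThreshold = 0.75) {
  summarise <- function(obs) {
    dt <- data.table::as.data.table(obs)[mod_state == "phospho"]
    dt <- merge(dt, .peptideAssignment(obs), by = "sequence")
    detected <- unique(dt$sequence)
    loc <- dt[loc_prob > locThreshold]
    localized <- unique(loc$sequence)
    quant <- unique(loc[quantified == TRUE & !is.na(intensity)]$sequence)
    list(detected = detected, localized = localized, quantified = quant,
         proteins = unique(loc$accession))
  }
  u <- summarise(untreatedObs)
  t <- summarise(treatedObs)
  list(
    untreated = lengths(u), treated = lengths(t),
    only_untreated = length(setdiff(u$localized, t$localized)),
    both = length(intersect(u$localized, t$localized)),
    only_treated = length(setdiff(t$localized, u$localized)),
    proteins_only_untreated = length(setdiff(u$proteins, t$proteins)),
    proteins_both = length(intersect(u$proteins, t$proteins)),
    proteins_only_treated = length(setdiff(t$proteins, u$proteins)))
}

#' Write / read a peptide observation table as TSV
#'
#' @param peptideObs Peptide observation data.frame.
#' @param path Output TSV path.
#' @return \code{writePeptideTable}: the path, invisibly;
#'   \code{readPeptideTable}: the data.frame.
#' @export
writePeptideTable <- function(peptideObs, path) {
  .writeTsv(peptideObs, path)
  invisible(path)
}

#' @rdname writePeptideTable
#' @export
readPeptideTable <- function(path) .readTsv(path)
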