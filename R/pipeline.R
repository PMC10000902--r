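#' Configuration for a full two-platform simulation study
#'
#' Bundles every knob of the study into one echoable object.  The defaults
#' describe the emulated study design: a proteome with on average three
#' proteoforms per canonical protein, six technical replicates of a pooled
#' sample and three biological replicates per platform, gel runs over the
#' pH 4--7 and 6--9 ranges with a Cy2 internal standard, and direct
#' (enrichment-free) shotgun acquisition.
#'
#' @param seed Master seed; every stochastic stage derives its own stream
#'   from it by fixed offsets.
#' @param nProteins Canonical proteins in the synthetic proteome.
#' @param meanProteoforms Mean proteoforms per protein.
#' @param phosphoFraction Fraction of extra proteoforms that are
#'   phosphorylation variants.
#' @param nTech Technical replicates (pooled sample).
#' @param nBio Biological replicates.
#' @param noise A \code{\link{noiseModel}}.
#' @param ppaseEfficiency Dephosphorylation efficiency of the phosphatase
#'   contrast.
#' @param ... Further arguments passed to \code{\link{generateProteome}}.
#' @return List of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1L, nProteins = 300,
                             meanProteoforms = 3, phosphoFraction = 0.5,
                             nTech = 6L, nBio = 3L, noise = noiseModel(),
                             ppaseEfficiency = 1, ...) {
  structure(list(seed = as.integer(seed), nProteins = nProteins,
                 meanProteoforms = meanProteoforms,
                 phosphoFraction = phosphoFraction, nTech = nTech,
                 nBio = nBio, noise = noise,
                 ppaseEfficiency = ppaseEfficiency,
                 proteomeExtra = list(...)),
            class = "SimulationConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

# matched SA tables for one replicate set, composed over pH ranges
.digeArm <- function(model, spots, abund, noise, seed) {
  design <- gelDesign(colnames(abund))
  obs <- simulateGels(spots, abund, design, noise, seed = seed)
  sa <- standardizeAbundance(obs, design)
  matched <- matchSpots(sa, design)
  list(design = design, obs = sa, matched = matched)
}

#' Run the full comparative simulation study
#'
#' Composes every stage of the package into the headline pipeline: proteome
#' generation, per-replicate abundances, gel simulation with
#' internal-standard standardization and cross-replicate matching, shotgun
#' simulation with protein-group inference and LFQ/iBAQ, variation
#' summaries on both platforms (technical and total), reproducibility
#' counts, spot-level and proteoform-summed cross-platform correlations,
#' the phosphatase contrast on both platforms, and the workload report.
#' Fully reproducible from the configuration's seed.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param outDir Optional output directory: tables are written as TSV, the
#'   summary as JSON and the configuration echo as YAML.
#' @return List of class \code{SimulationStudy} with elements \code{model},
#'   \code{dige}, \code{shotgun}, \code{phospho}, \code{workload} and
#'   \code{summary} (flat named list of the headline statistics).
#' @export
runSimulationStudy <- function(config = simulationConfig(), outDir = NULL) {
  seed <- config$seed
  noise <- config$noise
  model <- .stage("proteome", generateProteome(
    nProteins = config$nProteins, meanProteoforms = config$meanProteoforms,
    phosphoFraction = config$phosphoFraction, seed = seed))
  spots <- .stage("spot formation", formSpots(model, gelDesign("x")))

  ## 2D-DIGE arm
  abundDigeTech <- .stage("replicate abundances",
                          sampleReplicateAbundances(model, 1L, config$nTech,
                                                    noise, "dige",
                                                    seed = seed + 101L))
  digeTech <- .stage("dige technical", .digeArm(model, spots, abundDigeTech,
                                                noise, seed + 102L))
  abundDigeBio <- sampleReplicateAbundances(model, config$nBio, 1L, noise,
                                            "dige", seed = seed + 103L)
  digeBio <- .stage("dige biological", .digeArm(model, spots, abundDigeBio,
                                                noise, seed + 104L))
  cvDigeTech <- summarizeVariation(digeTech$matched@sa, "2D-DIGE", "tech")
  cvDigeTotal <- summarizeVariation(digeBio$matched@sa, "2D-DIGE", "total")
  ranges <- split.data.frame(digeTech$matched@sa,
                             digeTech$matched@spots$ph_range)
  repro <- reproducibleEntities(ranges)
  spotSizes <- reconstructSpotVolume(digeTech$matched)
  spotSizes$accession <- spots$accession[match(spotSizes$spot_id,
                                               spots$spot_id)]

  ## shotgun arm
  params <- shotgunParams()
  abundSgTech <- sampleReplicateAbundances(model, 1L, config$nTech, noise,
                                           "shotgun", seed = seed + 201L)
  runsTech <- .stage("shotgun technical",
                     simulateShotgunRuns(model, abundSgTech, params, noise,
                                         seed = seed + 202L))
  lfqTech <- computeLfq(runsTech)
  lfqMatTech <- .lfqMatrix(lfqTech)
  cvSgTech <- summarizeVariation(lfqMatTech, "shotgun", "tech")
  abundSgBio <- sampleReplicateAbundances(model, config$nBio, 1L, noise,
                                          "shotgun", seed = seed + 203L)
  runsBio <- .stage("shotgun biological",
                    simulateShotgunRuns(model, abundSgBio, params, noise,
                                        seed = seed + 204L))
  cvSgTotal <- summarizeVariation(.lfqMatrix(computeLfq(runsBio)),
                                  "shotgun", "total")
  groups <- inferProteinGroups(runsTech, model)

  ## cross-platform correlation
  lfqMean <- data.frame(accession = rownames(lfqMatTech),
                        lfq = rowMeans(lfqMatTech, na.rm = TRUE),
                        stringsAsFactors = FALSE)
  corSummed <- proteoformSumCorrelation(spotSizes, lfqMean, "summed")
  corPerSpot <- proteoformSumCorrelation(spotSizes, lfqMean, "per-spot")

  ## phosphatase contrast, both platforms
  contrast <- .stage("ppase contrast",
                     simulatePpaseContrast(model, digeTech$design, noise,
                                           config$ppaseEfficiency,
                                           seed = seed + 301L))
  calls <- ppaseRatioClassify(contrast)
  frac <- phosphoFraction(sum(calls$flagged), nrow(calls))
  treatedModel <- dephosphorylate(model, config$ppaseEfficiency)
  abundTreated <- sampleReplicateAbundances(treatedModel, 1L, 2L, noise,
                                            "shotgun", seed = seed + 302L)
  runsTreated <- .stage("shotgun treated",
                        simulateShotgunRuns(treatedModel, abundTreated,
                                            params, noise,
                                            seed = seed + 303L))
  phosAcc <- phosphositeAccounting(runsTech, runsTreated)
  nIdentified <- length(unique(groups$accession))
  phosphoProteins <- unique(.phosphoProteins(runsTech))
  ibaq <- computeIbaq(runsTech, model, params$rule)
  ppep <- .phosphoIntensities(runsTech)
  ratios <- ibaqPpeptideRatio(ppep, ibaq)

  ## workload
  preset <- timingPreset("du145-2023")
  sr <- speedRatio(preset$dige, preset$shotgun)

  summary <- list(
    n_proteins = nProteins(model), n_proteoforms = nProteoforms(model),
    n_spots = nrow(spots),
    multi_proteoform_spot_fraction = mean(spots$n_proteoforms > 1L),
    repro_counts = as.list(repro),
    median_cv_tech_dige = cvDigeTech$median,
    median_cv_total_dige = cvDigeTotal$median,
    mean_cv_total_dige = cvDigeTotal$mean,
    median_cv_tech_shotgun = cvSgTech$median,
    median_cv_total_shotgun = cvSgTotal$median,
    n_protein_groups = nIdentified,
    spearman_summed = corSummed@rS, spearman_summed_n = corSummed@n,
    spearman_per_spot = corPerSpot@rS, spearman_per_spot_n = corPerSpot@n,
    phospho_flagged = sum(calls$flagged),
    phospho_fraction_pct = frac$percent,
    phospho_fraction_unrounded = frac$unrounded,
    phosphoprotein_pct_shotgun = 100 * length(phosphoProteins) / nIdentified,
    ppeptide_ibaq_fraction_below_1 = ratios$fractionBelow1,
    minutes_per_entity_dige = perEntityMinutes(preset$dige),
    minutes_per_entity_shotgun = perEntityMinutes(preset$shotgun),
    speed_ratio = sr$ratio,
    seed = seed)

  out <- list(model = model, spots = spots,
              dige = list(tech = digeTech, bio = digeBio,
                          cvTech = cvDigeTech, cvTotal = cvDigeTotal,
                          spotSizes = spotSizes),
              shotgun = list(groups = groups, lfq = lfqTech,
                             cvTech = cvSgTech, cvTotal = cvSgTotal,
                             ibaq = ibaq),
              phospho = list(contrast = contrast, calls = calls,
                             fraction = frac, accounting = phosAcc,
                             ratios = ratios),
              workload = preset,
              correlations = list(summed = corSummed, perSpot = corPerSpot),
              config = config, summary = summary)
  class(out) <- "SimulationStudy"
  if (!is.null(outDir)) writeStudyOutputs(out, outDir)
  out
}

#' One replicate of the proteoform-summing correlation experiment
#'
#' A compact pipeline replicate used to study the direction of the
#' summing effect: simulate a small proteome through both platforms and
#' return the per-spot and proteoform-summed Spearman correlations between
#' DIGE spot sizes and shotgun LFQ.  Designed to be cheap enough to repeat
#' hundreds of times.
#'
#' @param seed Integer seed for this replicate.
#' @param nProteins Proteome size per replicate.
#' @return Named numeric vector \code{c(summed = , perspot = )}.
#' @export
correlationDirectionReplicate <- function(seed, nProteins = 60) {
  m <- generateProteome(nProteins = nProteins, seed = seed)
  nm <- noiseModel()
  aD <- sampleReplicateAbundances(m, 1L, 3L, nm, "dige", seed = seed + 1L)
  design <- gelDesign(colnames(aD))
  spots <- formSpots(m, design)
  sa <- standardizeAbundance(simulateGels(spots, aD, design, nm,
                                          seed = seed + 2L), design)
  matched <- matchSpots(sa, design)
  sizes <- reconstructSpotVolume(matched)
  sizes$accession <- spots$accession[match(sizes$spot_id, spots$spot_id)]
  aS <- sampleReplicateAbundances(m, 1L, 2L, nm, "shotgun", seed = seed + 3L)
  runs <- simulateShotgunRuns(m, aS, shotgunParams(), nm, seed = seed + 4L)
  lfqMat <- .lfqMatrix(computeLfq(runs))
  lfqMean <- data.frame(accession = rownames(lfqMat),
                        lfq = rowMeans(lfqMat, na.rm = TRUE),
                        stringsAsFactors = FALSE)
  suppressMessages(c(
    summed = proteoformSumCorrelation(sizes, lfqMean, "summed")@rS,
    perspot = proteoformSumCorrelation(sizes, lfqMean, "per-spot")@rS))
}

.lfqMatrix <- function(lfq) {
  acc <- sort(unique(lfq$accession))
  runs <- sort(unique(lfq$run_id))
  m <- matrix(NA_real_, length(acc), length(runs),
              dimnames = list(acc, runs))
  m[cbind(match(lfq$accession, acc), match(lfq$run_id, runs))] <- lfq$lfq
  m
}

.phosphoProteins <- function(peptideObs) {
  obs <- peptideObs[peptideObs$mod_state == "phospho", , drop = FALSE]
  if (!nrow(obs)) return(character())
  asg <- .peptideAssignment(peptideObs)
  asg$accession[match(unique(obs$sequence), asg$sequence)]
}

.phosphoIntensities <- function(peptideObs) {
  obs <- peptideObs[peptideObs$mod_state == "phospho" & peptideObs$quantified &
                      !is.na(peptideObs$intensity), , drop = FALSE]
  asg <- .peptideAssignment(peptideObs)
  data.frame(accession = asg$accession[match(obs$sequence, asg$sequence)],
             sequence = obs$sequence, intensity = obs$intensity,
             stringsAsFactors = FALSE)
}

#' @export
print.SimulationStudy <- function(x, ...) {
  s <- x$summary
  cat("Two-platform simulation study (seed", s$seed, ")\n")
  cat(sprintf("  proteome: %d proteins, %d proteoforms, %d gel spots\n",
              s$n_proteins, s$n_proteoforms, s$n_spots))
  cat(sprintf("  CV medians: DIGE tech %.1f%%, total %.1f%%; shotgun tech %.1f%%, total %.1f%%\n",
              s$median_cv_tech_dige, s$median_cv_total_dige,
              s$median_cv_tech_shotgun, s$median_cv_total_shotgun))
  cat(sprintf("  r_S summed %.3f (n=%d) vs per-spot %.3f (n=%d)\n",
              s$spearman_summed, s$spearman_summed_n, s$spearman_per_spot,
              s$spearman_per_spot_n))
  cat(sprintf("  phospho: %d spots flagged (%d%%); shotgun phosphoproteins %.2f%%\n",
              s$phospho_flagged, s$phospho_fraction_pct,
              s$phosphoprotein_pct_shotgun))
  invisible(x)
}

#' Write the outputs of a simulation study
#'
#' TSV tables, a JSON summary of the headline statistics and a YAML echo of
#' the configuration (seed included) into a directory.
#'
#' @param study Result of \code{\link{runSimulationStudy}}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeStudyOutputs <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  .writeTsv(study$spots, file.path(dir, "spot_map.tsv"))
  .writeTsv(study$dige$spotSizes, file.path(dir, "spot_sizes.tsv"))
  .writeTsv(study$shotgun$groups, file.path(dir, "protein_groups.tsv"))
  .writeTsv(study$shotgun$lfq, file.path(dir, "lfq.tsv"))
  .writeTsv(study$shotgun$ibaq, file.path(dir, "ibaq.tsv"))
  .writeTsv(as.data.frame(study$phospho$calls),
            file.path(dir, "phospho_calls.tsv"))
  jsonlite::write_json(study$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- study$config
  cfg$noise <- list(sigmaTechDige = cfg$noise@sigmaTechDige,
                    sigmaTechShotgun = cfg$noise@sigmaTechShotgun,
                    sigmaBioDige = cfg$noise@sigmaBioDige,
                    sigmaBioShotgun = cfg$noise@sigmaBioShotgun,
                    phosphoPenalty = cfg$noise@phosphoPenalty)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
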