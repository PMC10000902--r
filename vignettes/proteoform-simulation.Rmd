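---
title: "Simulating top-down and bottom-up proteoform quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating top-down and bottom-up proteoform quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProteoformSim)
```

## The problem

A gene's protein product rarely exists as a single molecular species.
Proteolytic processing, phosphorylation and other modifications produce
*proteoforms* — distinct intact molecules sharing one canonical sequence —
and the two standard quantitative proteomics platforms treat them in
fundamentally different ways.  Gel-based top-down 2D-DIGE separates intact
proteoforms by isoelectric point (pI) and molecular weight (MW) and
quantifies each resolved spot; gel-free bottom-up shotgun LC-MS/MS digests
everything into peptides first, and afterwards can only reassemble
*canonical* protein groups, erasing proteoform identity.  ProteoformSim
makes that contrast computable: it generates a ground-truth
proteoform-resolved proteome, pushes it through models of both measurement
processes, and computes the comparison statistics on the outputs, so every
claim about what each platform can and cannot see is a testable property
of code rather than an anecdote.

## The synthetic proteome

`generateProteome()` draws canonical sequences from average human residue
frequencies with log-normal lengths around 450 residues.  Each protein
receives `1 + Poisson(mean - 1)` proteoforms (default mean 3, the classic
2D-gel-era estimate for eukaryotes; a proteoform-atlas-scale proteome is a
single-knob change).  Extra forms are either

* **phosphorylation variants** — 1–3 phospho groups on S/T/Y sites, with a
  site occupancy drawn uniformly from `occupancyRange` (default
  0.05–0.95), or
* **cleavage variants** — one contiguous fragment after a cut at a
  uniformly random internal site, recorded as ground truth.

Base abundances are log-normal (`sdlog = 2`), spanning well over three
orders of magnitude, since only ratios and ranks are meaningful for either
platform.  pI is computed by bisection of the Henderson–Hasselbalch net
charge over the Bjellqvist pKa set (the de-facto standard of the
IPG-strip era), with phospho groups contributing a two-stage acid
(pKa 1.2 and 6.5); molecular weight is the standard residue-mass sum.
These tables ship as plain TSV under `inst/extdata/` so they are auditable
and swappable.

The generator is *not* a dial to be fitted: its defaults define the study
conditions, and the tests characterize the behaviour of the statistics
under exactly these conditions.

## Noise model and calibration

All noise is multiplicative log-normal, because coefficients of variation
(CVs) are scale-free percentages.  The platform sigmas are calibrated
through the closed form $CV = \sqrt{e^{\sigma^2}-1}$:

| quantity | sigma | implied CV |
|---|---|---|
| 2D-DIGE technical | 0.0759 | 7.6 % |
| shotgun technical | 0.2367 | 24 % |
| 2D-DIGE total (tech + bio) | 0.1295 | 13 % |
| shotgun total | 0.5466 | 59 % |

`sampleReplicateAbundances()` applies the biological deviation once per
biological replicate and the technical deviation per technical replicate,
so CV summaries computed downstream are calibrated directly against the
closed form.  The measurement simulators then add only structural effects
(detection, normalization, channel gains) by default; extra channel noise
is available but off, so the calibration stays exact at the abundance
level.

Two deliberate consequences are worth knowing.  First, the *realized*
median CV of a finite replicate set sits below the population value: with
$n = 6$ replicates the sample standard deviation is biased low by a few
percent, and with $n = 3$ and a large sigma the bias is severe — at
$\sigma = 0.5466$ the cohort mean of sample CVs lands near 45 %, not 59 %.
That is a property of the raw-scale sample CV itself at tiny $n$, not of
the simulation, and the package reports what the estimator actually
produces rather than the asymptote.  Second, pipeline-level CVs sit
slightly above the abundance-level calibration on the DIGE side (the
per-channel normalization set fluctuates with detection) and well above it
on the shotgun side, where the stochastically varying set of detected
peptides feeds directly into the LFQ sum — the same mechanism that makes
real label-free data noisy in the absence of an internal standard.

## The 2D-DIGE simulator

`formSpots()` merges proteoforms closer than `deltaPi = 0.05` pH units
*and* 2 % relative MW into single spots (finite gel resolution), drops
forms outside every pH range, and keeps contributing form ids as ground
truth.  Spots are assigned to the first listed range containing their pI,
so the default 4–7 / 6–9 pair acts as a partition and composed counts add
without double counting.

`simulateGels()` realises the classic design: two sample channels (Cy3,
Cy5) plus the pooled internal standard (IS) on Cy2 of every gel, each gel
run per pH range.  Detection is Bernoulli with probability logistic in log
volume (weak spots go missing more often) and a penalty factor on the
technically harder 6–9 range.  `standardizeAbundance()` computes the DIGE
quantity: a spot's channel-normalized volume divided by the same spot's
normalized volume in the gel's IS channel.  SA is exactly 1 on the IS
channel, invariant to channel gains, and undefined (missing, never
imputed) when the IS missed the spot.

`matchSpots()` performs DeCyder-style master matching: the first
replicate is the master list and every other replicate is matched greedily
to the nearest master spot within tolerance, per pH range.  Everything
downstream uses only the 100 %-matched subset — no imputation exists
anywhere in the package, mirroring how reproducibility-restricted analyses
are done on real gel data.

## The shotgun simulator

`simulateShotgunRuns()` digests every proteoform with the trypsin/Lys-C
rule into the shared peptide pool (intensity book-keeping uses the fully
cleaved peptides, so each molecule is counted exactly once; the
missed-cleavage enumeration up to 2 sites exists for the identification
surface of `digestSequence()`).  A peptide's true intensity sums all
contributing proteoforms — this is where proteoform identity dies — with
phospho occupancy splitting site-bearing peptides into modified and
unmodified states.  Each unique peptide carries a fixed log-normal
ionization factor, and data-dependent acquisition is emulated by a
logistic-in-log-intensity detection curve rather than explicit top-10
queues: that reproduces the analysis-relevant signature (intensity-
dependent stochastic missingness) at desk scale.  Direct (enrichment-free)
phosphopeptide detection is penalized by a factor of 0.005, calibrated so
that under the default proteome fewer than 1 % of identified proteins show
any phosphopeptide.

`inferProteinGroups()` reassembles peptides to canonical accessions
(shared peptides go to the accession with more distinct peptides, ties
lexicographic).  `computeLfq()` scales runs by the median peptide ratio to
a reference run and sums normalized intensities per group — deliberately
*not* the full MaxLFQ pairwise least-squares system: the comparison only
needs a scale-free protein intensity with the right invariances
(single-run sum, exact invariance to run-wide intensity scaling), and the
simplification is prominent in the documentation by design.
`computeIbaq()` divides summed intensities by the count of theoretically
measurable fully-cleaved peptides (6–30 residues, the common convention;
configurable because no universal definition exists).

## The phosphatase contrast

Lambda phosphatase removes phosphate groups; losing a phosphate raises a
protein's pI, so an untreated/treated channel pair turns phosphoproteoforms
into position-shifted spot pairs.  Two operations model this at different
levels:

* `dephosphorylate()` transforms the *model*: occupancies are scaled by
  `1 - efficiency`, and a form reaching occupancy 0 is chemically
  identical to its unmodified twin and merges into it.  Per-parent totals
  are conserved exactly and merged material always moves to an equal or
  higher pI.
* `simulatePpaseContrast()` produces the *gel-level* pair.  Each spot's
  treated volume keeps the material not dephosphorylated,
  $V(1 - e\,\bar o)$ with $\bar o$ the spot's abundance-weighted phospho
  occupancy, and the removed mass is booked at the dephosphorylated
  species' coordinates as treated-only positions.  Keeping re-migrated
  material off the untreated positions makes the spot-level ratio exactly
  the occupancy algebra $1/(1 - e\,\bar o)$, so the classifier threshold
  has a closed-form oracle: at full efficiency a spot is flagged at the
  default strict threshold of 1.5 iff $\bar o > 1/3$.  The price is that
  the treated channel shows dephosphorylated material as separate
  positions rather than merged into existing unmodified spots — a
  deliberate simplification chosen to keep the classification algebra
  exact and testable.

`ppaseRatioClassify()` applies the strict `ratio > 1.5` rule, with a
"fully shifted" branch (no division) for spots whose treated volume falls
below the detection floor.  `phosphoFraction()` rounds the headline
percentage half-up to an integer, the convention used when such screens
are reported.

## Statistics

`coefficientOfVariation()` is the raw-scale percent CV with the sample
(n−1) standard deviation — the denominator choice matters at n = 3 and 6,
so it is documented and configurable.  `cvOnLog2()` exists to demonstrate
a methodological trap: applying the CV formula to log2-transformed
intensities systematically understates multiplicative variability, and the
function therefore warns and flags its result as non-comparable.  The
property suite shows the log2-scale value is smaller in essentially every
simulated entity whenever the raw CV exceeds a few percent.

`spearmanRank()` is Pearson on midranks.  Midranks are not optional here:
the per-spot cross-platform comparison pairs several spots of one protein
with a single repeated LFQ value, which forces ties in one argument.
`proteoformSumCorrelation()` runs the comparison at both levels — per spot,
and after summing spot volumes per protein, the level at which the two
platforms finally measure the same object.  Cohort summaries report both
median and mean: technical CV cohorts are conventionally summarized by the
median, totals by the mean, and both are always available.

`reproducibleEntities()` counts complete rows per pH range and composes
by summation; `timingPreset("du145-2023")` carries the workload
arithmetic of a real two-platform study (327 h / 144 spots vs 77 h / 703
proteins) as components, so the headline 136 vs 6.6 minutes per protein
and the 20-fold ratio regenerate from inputs rather than being stored.

## The packaged spot catalog

`loadSpotCatalog()` ships a transcription of a published 36-spot,
11-protein comparison of mutually identified entities in the DU145
proteome (2D-DIGE spot sizes and CVs against shotgun LFQ and CVs).  The
two CALM1 spots are flagged excluded — that protein was only detectable in
its phosphorylated state — leaving 34 spots on 10 proteins;
`runSpotCatalogReport()` then reproduces the published rank correlations
(summed $r_S = 0.758$, $n = 10$; per-spot $r_S \approx 0.375$, $n = 34$;
the per-spot value recomputed from rounded printed numbers lands at 0.380,
which is why the tests assert a ±0.01 band rather than an exact match).
Transcription anomalies are preserved, not fixed: the duplicated printed
spot label "31" is kept in `label_as_printed` beside unique ids, and an
internal inconsistency of the source for the YWHAG CVs is carried
verbatim.  The fixture is checksummed in the test suite.

## Problem sizes and reproducibility

Every stochastic function takes a seed, and `runSimulationStudy()` derives
per-stage streams from one master seed, echoing the full configuration
into its outputs.  The shipped analyses use proteomes of 300–400 proteins
(about 1 000–1 200 proteoforms) for CV work, 60-protein replicates
repeated 200 times for the correlation-direction experiment, and a
10 000-protein run for the rare-event phosphoprotein calibration; these
sizes were chosen so that Monte-Carlo error is comfortably inside each
statistic's tolerance while a full study stays interactive on a laptop.

## What passing tests do and do not show

The generator emulates the features the statistics are sensitive to —
abundance dynamic range, proteoform multiplicity, pI/MW shifts from
phosphorylation and cleavage, multiplicative technical and biological
noise, intensity-dependent missingness, and the rarity of direct
phosphopeptide detection.  It does not model splice-isoform graphs, gel
image artefacts (dust, streaks, spot splitting), retention-time drift,
match-between-runs, spectral identification error, or FDR control.
Consequently, passing tests validate the *statistical machinery and its
documented properties*, and the qualitative platform contrasts; they do
not certify absolute counts from any particular real experiment, which
depend on instruments and image analysis that this package deliberately
does not simulate.
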