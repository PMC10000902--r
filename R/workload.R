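#' Workflow timing for per-protein workload accounting
#'
#' A named set of workflow steps, each with a duration in hours and a
#' hands-on fraction, plus the number of entities (spots or proteins) the
#' workflow quantified and identified.
#'
#' @param steps data.frame with columns \code{step}, \code{hours},
#'   \code{hands_on_fraction}.
#' @param entities Number of quantified + identified entities (>= 1).
#' @param label Free-text label.
#' @return List of class \code{WorkflowTiming}.
#' @export
workflowTiming <- function(steps, entities, label = "") {
  stopifnot(all(c("step", "hours", "hands_on_fraction") %in% names(steps)))
  if (any(steps$hours < 0)) stop("invalid input: durations must be >= 0")
  if (any(steps$hands_on_fraction < 0 | steps$hands_on_fraction > 1))
    stop("invalid input: hands-on fractions must lie in [0, 1]")
  if (entities < 1) stop("invalid input: entity count must be >= 1")
  structure(list(steps = steps, entities = as.numeric(entities),
                 label = label), class = "WorkflowTiming")
}

#' @export
print.WorkflowTiming <- function(x, ...) {
  tot <- sum(x$steps$hours)
  cat(sprintf("WorkflowTiming [%s]: %.0f h over %d steps, %g entities (%s min/entity)\n",
              x$label, tot, nrow(x$steps), x$entities,
              formatMinutes(perEntityMinutes(tot, x$entities))))
  invisible(x)
}

#' Shipped timing presets
#'
#' \code{"du145-2023"} encodes the workload of a full two-platform study of
#' the DU145 proteome: the gel side took 327 h in total (183 h of gel work
#' and 144 h of spot digestion plus MS identification, about half of it
#' hands-on) for 144 identified spots, and the shotgun side 77 h (about 10\%
#' hands-on) for 703 reliably quantified proteins.  The headline figures --
#' 136 min versus 6.6 min per protein, a 20-fold speed difference --
#' regenerate from these components.
#'
#' @param name Preset name.
#' @return List with elements \code{dige} and \code{shotgun}, both
#'   \code{\link{workflowTiming}} objects.
#' @export
timingPreset <- function(name = "du145-2023") {
  if (name != "du145-2023") stop("unknown preset: ", name)
  list(
    dige = workflowTiming(
      data.frame(step = c("gel work", "spot digestion + MS identification"),
                 hours = c(183, 144), hands_on_fraction = c(0.5, 0.5),
                 stringsAsFactors = FALSE),
      entities = 144, label = "2D-DIGE du145-2023"),
    shotgun = workflowTiming(
      data.frame(step = c("sample preparation", "LC-MS/MS runs + analysis"),
                 hours = c(7.7, 69.3), hands_on_fraction = c(1, 0),
                 stringsAsFactors = FALSE),
      entities = 703, label = "shotgun du145-2023"))
}

#' Minutes of analysis time per quantified entity
#'
#' @param hours Total workflow hours (>= 0), or a
#'   \code{\link{workflowTiming}} (entities then taken from it).
#' @param entities Entity count (>= 1).
#' @return Minutes per entity, unrounded.
#' @examples
#' perEntityMinutes(327, 144)  # 136.25
#' perEntityMinutes(77, 703)   # 6.57...
#' @export
perEntityMinutes <- function(hours, entities) {
  if (inherits(hours, "WorkflowTiming")) {
    entities <- hours$entities
    hours <- sum(hours$steps$hours)
  }
  if (entities < 1) stop("invalid input: entity count must be >= 1")
  if (hours < 0) stop("invalid input: hours must be >= 0")
  60 * hours / entities
}

#' Format minutes at reporting precision
#'
#' Integer minutes for values of 100 and above, one decimal below.
#'
#' @param minutes Numeric.
#' @return Character.
#' @export
formatMinutes <- function(minutes) {
  ifelse(minutes >= 100, sprintf("%.0f", minutes), sprintf("%.1f", minutes))
}

#' Fold difference in per-entity analysis time
#'
#' @param a,b \code{\link{workflowTiming}} objects (ratio a/b).
#' @return List with \code{ratio} (unrounded) and \code{atLeastFold}
#'   (\code{floor(ratio)}).
#' @export
speedRatio <- function(a, b) {
  r <- perEntityMinutes(a) / perEntityMinutes(b)
  list(ratio = r, atLeastFold = floor(r))
}

#' Hands-on time of a workflow
#'
#' @param timing A \code{\link{workflowTiming}}.
#' @return List with \code{hours} (sum of duration x hands-on fraction),
#'   \code{totalHours} and \code{fraction}.
#' @export
handsOnSummary <- function(timing) {
  h <- sum(timing$steps$hours * timing$steps$hands_on_fraction)
  tot <- sum(timing$steps$hours)
  list(hours = h, totalHours = tot, fraction = if (tot > 0) h / tot else 0)
}
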