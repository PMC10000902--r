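#' Coefficient of variation on the raw scale
#'
#' \eqn{100 \cdot s / \bar{x}} with the sample (n-1) standard deviation,
#' computed on untransformed values.  This is the scale on which platform
#' variability is comparable across methods; see \code{\link{cvOnLog2}} for
#' why the popular log2-scale shortcut is not.
#'
#' @param values Positive numeric vector, length >= 2.
#' @param denominator \code{"n-1"} (default) or \code{"n"}.
#' @return CV in percent.
#' @examples
#' coefficientOfVariation(c(8, 10, 12))  # 20
#' @export
coefficientOfVariation <- function(values, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  if (length(values) < 2L) stop("invalid input: need at least 2 values")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("invalid input: values must be positive and finite")
  s <- stats::sd(values)
  if (denominator == "n")
    s <- s * sqrt((length(values) - 1) / length(values))
  100 * s / mean(values)
}

#' CV computed on log2-transformed values (deliberately wrong)
#'
#' Applies the CV formula to log2-transformed values.  This is a common
#' shortcut in the label-free literature and it systematically understates
#' the variability: for multiplicative data the log2 "CV" shrinks as the
#' signal grows and is not comparable to a raw-scale CV.  The function
#' exists to demonstrate that, and attaches a \code{"log2_scale"} attribute
#' flagging the value as non-comparable.
#'
#' @param values Numeric vector with all values > 1 (so the logs are
#'   positive and the formula is at least well defined).
#' @return Percent value with attribute \code{log2_scale = TRUE}, emitted
#'   with a warning.
#' @export
cvOnLog2 <- function(values) {
  if (length(values) < 2L) stop("invalid input: need at least 2 values")
  if (any(values <= 1))
    stop("domain error: log2-scale CV requires all values > 1")
  out <- coefficientOfVariation(log2(values))
  attr(out, "log2_scale") <- TRUE
  warning("CV computed on log2-transformed values is not comparable to a raw-scale CV",
          call. = FALSE)
  out
}

#' Per-entity variation summary
#'
#' Computes the raw-scale CV for every entity (spot or protein group) over
#' the replicate columns of a matrix, restricted to entities with complete
#' data (a missing value excludes the entity, with a logged count; nothing
#' is imputed), and reports cohort medians and means.
#'
#' @param mat Numeric matrix, entities x replicates, \code{NA} = missing.
#' @param method Label carried through (\code{"2D-DIGE"} or
#'   \code{"shotgun"}).
#' @param kind Label for the CV flavour (\code{"tech"} or \code{"total"}).
#' @return List of class \code{VariationSummary}: \code{perEntity}
#'   (data.frame entity_id, cv), \code{median}, \code{mean}, \code{n},
#'   \code{nExcluded}, \code{method}, \code{kind}, \code{nReplicates}.
#' @export
summarizeVariation <- function(mat, method = "2D-DIGE", kind = "tech") {
  stopifnot(is.matrix(mat), ncol(mat) >= 2L)
  complete <- stats::complete.cases(mat)
  nExcluded <- sum(!complete)
  if (nExcluded)
    message(nExcluded, " entities with missing values excluded from CV summary")
  m <- mat[complete, , drop = FALSE]
  cv <- apply(m, 1L, coefficientOfVariation)
  out <- list(perEntity = data.frame(entity_id = rownames(m) %||%
                                       as.character(seq_len(nrow(m))),
                                     cv = unname(cv),
                                     stringsAsFactors = FALSE),
              median = stats::median(cv), mean = mean(cv), n = nrow(m),
              nExcluded = nExcluded, method = method, kind = kind,
              nReplicates = ncol(mat))
  class(out) <- "VariationSummary"
  out
}

#' @export
print.VariationSummary <- function(x, ...) {
  cat(sprintf("VariationSummary [%s, CV_%s]: n = %d (excluded %d), median %.1f%%, mean %.1f%%\n",
              x$method, x$kind, x$n, x$nExcluded, x$median, x$mean))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count entities reproduced in every replicate
#'
#' An entity (spot or protein) counts as reproducible only when it is
#' present in every replicate column.  With several disjoint pH ranges the
#' composed count is the sum of the per-range counts.
#'
#' @param mat Matrix with \code{NA} marking missing entries, or a named
#'   list of such matrices (one per pH range).
#' @return For a matrix, the integer count; for a list, a named vector of
#'   per-range counts plus \code{composed}.
#' @examples
#' reproducibleEntities(list(`4-7` = matrix(1, 1070, 6),
#'                           `6-9` = matrix(1, 853, 6)))
#' @export
reproducibleEntities <- function(mat) {
  if (is.list(mat) && !is.data.frame(mat)) {
    per <- vapply(mat, function(m) sum(stats::complete.cases(m)), integer(1L))
    return(c(per, composed = sum(per)))
  }
  sum(stats::complete.cases(mat))
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks (average ranks for ties), the form
#' required when protein-level values are repeated against several spots of
#' the same protein.  Reduces to \eqn{1 - 6\sum d^2 / (n(n^2-1))} in the
#' tie-free case.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return \eqn{r_S} in [-1, 1].
#' @export
spearmanRank <- function(x, y) {
  if (length(x) != length(y)) stop("invalid input: x and y differ in length")
  if (length(x) < 3L) stop("invalid input: need n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("invalid input: non-finite values")
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

#' CorrelationResult class
#'
#' @slot rS Spearman rank correlation.
#' @slot n Number of pairs.
#' @slot level \code{"per-spot"} or \code{"per-protein-summed"}.
#' @slot entities Entity ids used.
#' @export
setClass("CorrelationResult",
  representation(rS = "numeric", n = "integer", level = "character",
                 entities = "character"),
  validity = function(object) {
    if (abs(object@rS) > 1 + 1e-12) return("|r_S| must be <= 1")
    if (object@n < 3L) return("n must be >= 3")
    TRUE
  })

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("CorrelationResult [%s]: r_S = %.3f, n = %d\n",
              object@level, object@rS, object@n))
})

#' Spot-level vs proteoform-summed cross-platform correlation
#'
#' Correlates top-down spot volumes with bottom-up protein quantities at
#' two levels.  Per-spot: every spot's volume is paired with the LFQ of its
#' parent protein (the LFQ value is repeated across the protein's spots;
#' midranks absorb the ties).  Summed: spot volumes are first summed per
#' protein, giving one pair per protein -- the level at which the two
#' platforms measure the same thing.
#'
#' @param spotVolumes data.frame with \code{spot_id}, \code{accession},
#'   \code{spot_size} (e.g. from \code{\link{reconstructSpotVolume}} plus a
#'   spot-to-protein mapping).
#' @param proteinQuant data.frame with \code{accession} and the protein
#'   quantity column named by \code{quantColumn}.
#' @param level \code{"summed"} (default) or \code{"per-spot"}.
#' @param quantColumn Name of the protein quantity column (default
#'   \code{"lfq"}).
#' @return A \code{\link{CorrelationResult-class}}.  Spots whose accession
#'   is absent from the protein table are excluded with a logged count.
#' @export
proteoformSumCorrelation <- function(spotVolumes, proteinQuant,
                                     level = c("summed", "per-spot"),
                                     quantColumn = "lfq") {
  level <- match.arg(level)
  stopifnot(all(c("accession", "spot_size") %in% names(spotVolumes)),
            all(c("accession", quantColumn) %in% names(proteinQuant)))
  q <- stats::setNames(proteinQuant[[quantColumn]], proteinQuant$accession)
  mapped <- spotVolumes$accession %in% names(q)
  if (any(!mapped))
    message(sum(!mapped), " spots without a protein-level quantification excluded")
  sv <- spotVolumes[mapped, , drop = FALSE]
  if (level == "summed") {
    sums <- tapply(sv$spot_size, sv$accession, sum)
    res <- spearmanRank(as.vector(sums), q[names(sums)])
    new("CorrelationResult", rS = res, n = length(sums),
        level = "per-protein-summed", entities = names(sums))
  } else {
    res <- spearmanRank(sv$spot_size, q[sv$accession])
    new("CorrelationResult", rS = res, n = nrow(sv), level = "per-spot",
        entities = if ("spot_id" %in% names(sv)) as.character(sv$spot_id)
                   else character())
  }
}
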