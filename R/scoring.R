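#' Map a raw metric value onto the 1-5 score scale
#'
#' Four strictly increasing cut points partition the metric range into
#' five bands.  For a higher-is-better metric, a value below the first
#' cut scores 1 and a value at or above the fourth scores 5, with
#' half-open bands `[b_i, b_{i+1})` scoring 2-4 in between; a
#' lower-is-better metric uses the mirror image.  The mapping is
#' deterministic and monotone in the value.
#'
#' @param value numeric vector of finite metric values.
#' @param direction `"higher"` or `"lower"`.
#' @param bands numeric vector of four strictly increasing cut points.
#' @return integer scores in 1..5, same length as `value`.
#' @examples
#' scoreMetric(0.5, "higher", c(0.2, 0.4, 0.6, 0.8))  # 3
#' scoreMetric(0.1, "lower", c(0.2, 0.4, 0.6, 0.8))   # 5
#' @export
scoreMetric <- function(value, direction = c("higher", "lower"), bands) {
  direction <- match.arg(direction)
  if (any(!is.finite(value)))
    stop("non-finite metric value cannot be scored", call. = FALSE)
  if (length(bands) != 4 || any(diff(bands) <= 0))
    stop("bands must be four strictly increasing cut points",
         call. = FALSE)
  raw <- findInterval(value, bands, left.open = FALSE) + 1L  # 1..5
  if (direction == "lower") raw <- 6L - raw
  as.integer(raw)
}

#' Weighted-average aggregation of scores
#'
#' The score of a subcharacteristic is the weighted average of its metric
#' scores, and the score of a characteristic is the weighted average of
#' its subcharacteristic scores; the result always lies between the
#' smallest and largest input score.
#'
#' @param scores numeric vector of scores in `[1, 5]`.
#' @param weights nonnegative weights with a positive sum; matched to
#'   `scores` by name when both are named.
#' @return the weighted mean score.
#' @examples
#' scoreAggregate(c(4, 2), c(0.5, 0.5))  # 3
#' @export
scoreAggregate <- function(scores, weights) {
  if (length(weights) != length(scores))
    stop("scores and weights must have equal length", call. = FALSE)
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be nonnegative with a positive sum",
         call. = FALSE)
  if (!is.null(names(weights)) && !is.null(names(scores)))
    scores <- scores[names(weights)]
  sum(weights * scores) / sum(weights)
}

#' Score a metric vector through a quality model
#'
#' @param mv a [MetricVector].
#' @param model a [QualityModel].
#' @return named integer vector of metric scores; degenerate metrics
#'   (zero denominator) score 1.
#' @keywords internal
scoreMetricVector <- function(mv, model) {
  m <- model@metrics
  out <- setNames(integer(nrow(m)), m$metric)
  vals <- metricValues(mv)
  for (i in seq_len(nrow(m))) {
    nm <- m$metric[[i]]
    if (nm %in% degenerateMetrics(mv)) {
      out[[nm]] <- 1L
    } else {
      out[[nm]] <- scoreMetric(vals[[nm]], m$direction[[i]],
                               as.numeric(m[i, c("b1", "b2", "b3", "b4")]))
    }
  }
  out
}

#' Evaluate an ontology against a quality model
#'
#' Composes [computeMetrics()], [scoreMetric()] and [scoreAggregate()]:
#' raw metric values are banded onto the integer 1-5 scale, then averaged
#' (with the model's weights) into real-valued subcharacteristic scores
#' and characteristic scores.  Metrics with a zero denominator score 1
#' and are flagged on the returned card rather than aborting.
#'
#' @param g an [OntologyGraph].
#' @param model a [QualityModel]; defaults to [defaultQualityModel()].
#' @param rfcInherited passed to [computeMetrics()].
#' @return a [ScoreCard] with all three score levels plus the raw
#'   [MetricVector].
#' @examples
#' g <- generateOntology(generatorSpec(nClasses = 15, seed = 3))
#' card <- evaluateOntology(g)
#' characteristicScores(card)
#' @export
evaluateOntology <- function(g, model = defaultQualityModel(),
                             rfcInherited = FALSE) {
  stopifnot(is(g, "OntologyGraph"), is(model, "QualityModel"))
  mv <- computeMetrics(g, rfcInherited = rfcInherited)
  mScores <- scoreMetricVector(mv, model)
  sScores <- vapply(model@subcharacteristics, function(w)
    scoreAggregate(mScores[names(w)], w), numeric(1))
  cScores <- vapply(model@characteristics, function(w)
    scoreAggregate(sScores[names(w)], w), numeric(1))
  new("ScoreCard", metricScores = mScores, subScores = sScores,
      charScores = cScores, metrics = mv,
      degenerate = degenerateMetrics(mv))
}
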