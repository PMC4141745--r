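#' @rdname OntologyGraph-class
#' @param x,object an object.
#' @export
setGeneric("ontologyClasses", function(x) standardGeneric("ontologyClasses"))

#' @rdname OntologyGraph-class
#' @export
setGeneric("subclassEdges", function(x) standardGeneric("subclassEdges"))

#' Assertion counts of an OntologyGraph
#'
#' Tally assertion occurrences (never declared entities): property usages
#' by kind (domain declarations plus occurrences in class restrictions),
#' anonymous restrictions, individual class-membership assertions and
#' class annotation assertions.
#'
#' @param x an [OntologyGraph].
#' @param kind for `propertyAssertions`, `"object"`, `"datatype"` or
#'   `"both"`.
#' @param perClass if `TRUE`, return a named integer vector over classes
#'   (summing to the total) instead of the total.
#' @return an integer total, or a named integer vector if
#'   `perClass = TRUE`.
#' @export
setGeneric("propertyAssertions",
  function(x, kind = c("both", "object", "datatype"), perClass = FALSE)
    standardGeneric("propertyAssertions"))

#' @rdname propertyAssertions
#' @export
setGeneric("restrictionAssertions", function(x, perClass = FALSE)
  standardGeneric("restrictionAssertions"))

#' @rdname propertyAssertions
#' @export
setGeneric("individualAssertions", function(x, perClass = FALSE)
  standardGeneric("individualAssertions"))

#' @rdname propertyAssertions
#' @export
setGeneric("annotationAssertions", function(x, perClass = FALSE)
  standardGeneric("annotationAssertions"))

#' @rdname MetricVector-class
#' @param x a [MetricVector].
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))

#' @rdname MetricVector-class
#' @export
setGeneric("degenerateMetrics", function(x)
  standardGeneric("degenerateMetrics"))

#' @rdname QualityModel-class
#' @param x a [QualityModel].
#' @export
setGeneric("subcharacteristicNames", function(x)
  standardGeneric("subcharacteristicNames"))

#' @rdname QualityModel-class
#' @export
setGeneric("characteristicNames", function(x)
  standardGeneric("characteristicNames"))

#' @rdname ScoreCard-class
#' @param x a [ScoreCard].
#' @export
setGeneric("metricScores", function(x) standardGeneric("metricScores"))

#' @rdname ScoreCard-class
#' @export
setGeneric("subcharacteristicScores", function(x)
  standardGeneric("subcharacteristicScores"))

#' @rdname ScoreCard-class
#' @export
setGeneric("characteristicScores", function(x)
  standardGeneric("characteristicScores"))

#' Long-format view of a ScoreCard
#'
#' @param x a [ScoreCard].
#' @return data.frame with columns `level` (`"metric"`,
#'   `"subcharacteristic"`, `"characteristic"`), `name` and `score`.
#' @export
setGeneric("scoreFrame", function(x) standardGeneric("scoreFrame"))

#' @rdname OntologyCohort-class
#' @param x an [OntologyCohort].
#' @export
setGeneric("cohortManifest", function(x) standardGeneric("cohortManifest"))

#' @rdname OntologyCohort-class
#' @export
setGeneric("cohortGraphs", function(x) standardGeneric("cohortGraphs"))

#' @rdname OntologyCohort-class
#' @export
setGeneric("goldStandards", function(x) standardGeneric("goldStandards"))
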