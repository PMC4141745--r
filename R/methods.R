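#' @rdname OntologyGraph-class
#' @export
setMethod("ontologyClasses", "OntologyGraph", function(x) x@classes)

#' @rdname OntologyGraph-class
#' @export
setMethod("subclassEdges", "OntologyGraph", function(x) x@edges)

perClassTally <- function(classes, hits) {
  out <- setNames(integer(length(classes)), classes)
  if (length(hits)) {
    tab <- table(hits)
    out[names(tab)] <- as.integer(tab)
  }
  out
}

#' @rdname propertyAssertions
#' @export
setMethod("propertyAssertions", "OntologyGraph",
  function(x, kind = c("both", "object", "datatype"), perClass = FALSE) {
    kind <- match.arg(kind)
    keep <- if (kind == "both") c("object", "datatype") else kind
    hits <- c(
      x@propertyDomains$class[x@propertyDomains$kind %in% keep],
      x@restrictions$class[x@restrictions$kind %in% keep]
    )
    if (perClass) perClassTally(x@classes, hits) else length(hits)
  })

#' @rdname propertyAssertions
#' @export
setMethod("restrictionAssertions", "OntologyGraph",
  function(x, perClass = FALSE) {
    if (perClass) perClassTally(x@classes, x@restrictions$class)
    else nrow(x@restrictions)
  })

#' @rdname propertyAssertions
#' @export
setMethod("individualAssertions", "OntologyGraph",
  function(x, perClass = FALSE) {
    if (perClass) perClassTally(x@classes, x@individuals$class)
    else nrow(x@individuals)
  })

#' @rdname propertyAssertions
#' @export
setMethod("annotationAssertions", "OntologyGraph",
  function(x, perClass = FALSE) {
    if (perClass) perClassTally(x@classes, x@annotations$class)
    else nrow(x@annotations)
  })

#' @rdname OntologyGraph-class
#' @export
setMethod("show", "OntologyGraph", function(object) {
  cat("OntologyGraph with", length(object@classes), "classes,",
      nrow(object@edges), "subclass edges\n")
  cat("  property assertions:", propertyAssertions(object),
      "| restrictions:", nrow(object@restrictions),
      "| individuals:", nrow(object@individuals),
      "| annotations:", nrow(object@annotations), "\n")
  if (!is.na(object@ontologyIRI))
    cat("  ontology IRI:", object@ontologyIRI, "\n")
})

#' @rdname MetricVector-class
#' @export
setMethod("metricValues", "MetricVector", function(x) x@values)

#' @rdname MetricVector-class
#' @export
setMethod("degenerateMetrics", "MetricVector", function(x) x@degenerate)

#' @rdname MetricVector-class
#' @export
setMethod("show", "MetricVector", function(object) {
  cat("MetricVector (12 structural metrics)\n")
  print(round(object@values, 4))
  if (length(object@degenerate))
    cat("  degenerate (zero denominator):",
        paste(object@degenerate, collapse = ", "), "\n")
})

#' @rdname QualityModel-class
#' @export
setMethod("subcharacteristicNames", "QualityModel",
  function(x) names(x@subcharacteristics))

#' @rdname QualityModel-class
#' @export
setMethod("characteristicNames", "QualityModel",
  function(x) names(x@characteristics))

#' @rdname QualityModel-class
#' @export
setMethod("show", "QualityModel", function(object) {
  cat("QualityModel:", nrow(object@metrics), "metrics ->",
      length(object@subcharacteristics), "subcharacteristics ->",
      length(object@characteristics), "characteristics\n")
})

#' @rdname ScoreCard-class
#' @export
setMethod("metricScores", "ScoreCard", function(x) x@metricScores)

#' @rdname ScoreCard-class
#' @export
setMethod("subcharacteristicScores", "ScoreCard", function(x) x@subScores)

#' @rdname ScoreCard-class
#' @export
setMethod("characteristicScores", "ScoreCard", function(x) x@charScores)

#' @rdname scoreFrame
#' @export
setMethod("scoreFrame", "ScoreCard", function(x) {
  data.frame(
    level = rep(c("metric", "subcharacteristic", "characteristic"),
                c(length(x@metricScores), length(x@subScores),
                  length(x@charScores))),
    name = c(names(x@metricScores), names(x@subScores),
             names(x@charScores)),
    score = c(as.numeric(x@metricScores), x@subScores, x@charScores),
    stringsAsFactors = FALSE
  )
})

#' @rdname ScoreCard-class
#' @export
setMethod("show", "ScoreCard", function(object) {
  cat("ScoreCard\n")
  cat("  characteristics:\n")
  for (nm in names(object@charScores))
    cat(sprintf("    %-22s %.2f\n", nm, object@charScores[[nm]]))
  cat("  (", length(object@subScores), "subcharacteristic and",
      length(object@metricScores), "metric scores; use scoreFrame() )\n")
  if (length(object@degenerate))
    cat("  degenerate metrics:",
        paste(object@degenerate, collapse = ", "), "\n")
})

#' @rdname OntologyCohort-class
#' @export
setMethod("cohortManifest", "OntologyCohort", function(x) x@manifest)

#' @rdname OntologyCohort-class
#' @export
setMethod("cohortGraphs", "OntologyCohort", function(x) x@graphs)

#' @rdname OntologyCohort-class
#' @export
setMethod("goldStandards", "OntologyCohort",
  function(x) list(manifest = x@goldManifest, graphs = x@goldGraphs))

#' @rdname OntologyCohort-class
#' @export
setMethod("show", "OntologyCohort", function(object) {
  m <- object@manifest
  cat("OntologyCohort:", nrow(m), "ontologies from",
      length(unique(m$student)), "students,",
      length(unique(m$topic)), "topics;",
      nrow(object@goldManifest), "gold standards\n")
  print(table(m$topic, m$arm))
})
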