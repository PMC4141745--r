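#' OntologyGraph: asserted content of an OWL ontology
#'
#' A metric-oriented view of an OWL 2 document: the named classes, the
#' asserted subclass edges between named classes, and per-class assertion
#' tables for property usage, anonymous restrictions, individual membership
#' and class annotations.  All quantities reflect assertion occurrences in
#' the document, never the number of declared entities, and exact duplicate
#' axioms are collapsed to one occurrence.
#'
#' Edges asserted directly under `owl:Thing` are kept apart in
#' `thingChildren`: they are excluded from the subclass-edge totals that
#' feed the metrics, but participate (together with the implicit rooting of
#' orphan classes) in root-to-leaf path computations.
#'
#' @slot classes character vector of named-class IRIs (never `owl:Thing`).
#' @slot edges data.frame with columns `child`, `parent`: asserted subclass
#'   axioms between named classes, one row per distinct axiom.
#' @slot thingChildren character vector of classes with an asserted
#'   `rdfs:subClassOf owl:Thing` axiom.
#' @slot propertyDomains data.frame (`property`, `class`, `kind`): property
#'   domain declarations; `kind` is `"object"` or `"datatype"`.
#' @slot restrictions data.frame (`class`, `property`, `kind`, `type`,
#'   `filler`, `axiom`): anonymous restriction expressions attached to a
#'   class through a subclass (`axiom = "subclass"`) or equivalence
#'   (`axiom = "equivalent"`) axiom; `type` is one of `"some"`, `"all"`,
#'   `"min"`, `"max"`, `"exact"`, `"hasValue"`.
#' @slot individuals data.frame (`individual`, `class`): class-membership
#'   assertions.
#' @slot annotations data.frame (`class`, `property`, `value`): annotation
#'   assertions whose subject is a named class.
#' @slot ontologyIRI length-one character, possibly `NA`.
#'
#' @seealso [parseOWL()], [writeOWL()], [computeMetrics()]
#' @export
setClass("OntologyGraph",
  representation(
    classes = "character",
    edges = "data.frame",
    thingChildren = "character",
    propertyDomains = "data.frame",
    restrictions = "data.frame",
    individuals = "data.frame",
    annotations = "data.frame",
    ontologyIRI = "character"
  ),
  prototype(
    classes = character(),
    edges = emptyEdges(),
    thingChildren = character(),
    propertyDomains = emptyDomains(),
    restrictions = emptyRestrictions(),
    individuals = emptyIndividuals(),
    annotations = emptyAnnotations(),
    ontologyIRI = NA_character_
  )
)

setValidity("OntologyGraph", function(object) {
  msgs <- character()
  e <- object@edges
  if (!all(c("child", "parent") %in% names(e)))
    msgs <- c(msgs, "edges must have columns child, parent")
  else {
    if (any(e$child == e$parent))
      msgs <- c(msgs, "subclass edge with child == parent")
    if (any(e$parent == OWL_THING))
      msgs <- c(msgs, "owl:Thing edges belong in thingChildren, not edges")
    bad <- setdiff(unique(c(e$child, e$parent)), object@classes)
    if (length(bad))
      msgs <- c(msgs, paste("edge endpoint not in classes:",
                            paste(bad, collapse = ", ")))
    if (anyDuplicated(e))
      msgs <- c(msgs, "duplicate subclass axioms must be collapsed")
  }
  if (length(setdiff(object@thingChildren, object@classes)))
    msgs <- c(msgs, "thingChildren must be members of classes")
  for (slotName in c("propertyDomains", "restrictions", "individuals",
                     "annotations")) {
    tab <- slot(object, slotName)
    if ("class" %in% names(tab) &&
        length(setdiff(unique(tab$class), object@classes)))
      msgs <- c(msgs, paste(slotName, "refers to an unknown class"))
  }
  if (any(duplicated(object@classes)))
    msgs <- c(msgs, "duplicate class IRIs")
  if (OWL_THING %in% object@classes)
    msgs <- c(msgs, "owl:Thing is the implicit root, not a member class")
  if (length(msgs)) msgs else TRUE
})

#' MetricVector: the twelve structural metric values of one ontology
#'
#' Holds LCOMOnto, WMCOnto, DITOnto, NACOnto, NOCOnto, RFCOnto, NOMOnto,
#' PROnto, AROnto, INROnto, CROnto and ANOnto as a named numeric vector,
#' plus the names of metrics whose denominator was zero (reported as 0 and
#' flagged degenerate rather than aborting the scoring pipeline).
#'
#' @slot values named numeric vector of length 12.
#' @slot degenerate character vector of metric names with a zero
#'   denominator.
#' @seealso [computeMetrics()]
#' @export
setClass("MetricVector",
  representation(values = "numeric", degenerate = "character"),
  prototype(values = setNames(numeric(12), c(
    "LCOMOnto", "WMCOnto", "DITOnto", "NACOnto", "NOCOnto", "RFCOnto",
    "NOMOnto", "PROnto", "AROnto", "INROnto", "CROnto", "ANOnto")),
    degenerate = character())
)

setValidity("MetricVector", function(object) {
  msgs <- character()
  if (!identical(sort(names(object@values)), sort(metricNames())))
    msgs <- c(msgs, "values must be named by the 12 metric names")
  if (any(!is.finite(object@values)))
    msgs <- c(msgs, "metric values must be finite")
  if (any(object@values < 0))
    msgs <- c(msgs, "metric values must be nonnegative")
  if (length(setdiff(object@degenerate, metricNames())))
    msgs <- c(msgs, "degenerate flags must name metrics")
  if (length(msgs)) msgs else TRUE
})

#' QualityModel: threshold bands and weighted aggregation structure
#'
#' The configurable quality model: per-metric score direction and threshold
#' bands (four strictly increasing cut points partitioning the metric range
#' into five score bands), a weighted metric list per subcharacteristic,
#' and a weighted subcharacteristic list per characteristic.  Weights are
#' normalized to sum to one at load time.  A metric may feed any number of
#' subcharacteristics.
#'
#' @slot metrics data.frame (`metric`, `direction`, `b1`..`b4`);
#'   `direction` is `"higher"` (larger is better) or `"lower"`.
#' @slot subcharacteristics named list of named numeric weight vectors over
#'   metrics.
#' @slot characteristics named list of named numeric weight vectors over
#'   subcharacteristics.
#' @seealso [readQualityModel()], [defaultQualityModel()]
#' @export
setClass("QualityModel",
  representation(metrics = "data.frame", subcharacteristics = "list",
                 characteristics = "list")
)

setValidity("QualityModel", function(object) {
  msgs <- character()
  m <- object@metrics
  need <- c("metric", "direction", "b1", "b2", "b3", "b4")
  if (!all(need %in% names(m)))
    return("metrics table must have columns metric, direction, b1..b4")
  if (!all(m$direction %in% c("higher", "lower")))
    msgs <- c(msgs, "direction must be 'higher' or 'lower'")
  cuts <- as.matrix(m[, c("b1", "b2", "b3", "b4")])
  if (any(t(apply(cuts, 1, diff)) <= 0))
    msgs <- c(msgs, "threshold cut points must be strictly increasing")
  for (s in names(object@subcharacteristics)) {
    w <- object@subcharacteristics[[s]]
    if (length(setdiff(names(w), m$metric)))
      msgs <- c(msgs, paste0("subcharacteristic '", s,
                             "' references an undefined metric"))
    if (any(w < 0) || sum(w) <= 0)
      msgs <- c(msgs, paste0("subcharacteristic '", s,
                             "' needs nonnegative weights with positive sum"))
  }
  for (ch in names(object@characteristics)) {
    w <- object@characteristics[[ch]]
    if (length(setdiff(names(w), names(object@subcharacteristics))))
      msgs <- c(msgs, paste0("characteristic '", ch,
                             "' references an undefined subcharacteristic"))
    if (any(w < 0) || sum(w) <= 0)
      msgs <- c(msgs, paste0("characteristic '", ch,
                             "' needs nonnegative weights with positive sum"))
  }
  if (length(msgs)) msgs else TRUE
})

#' ScoreCard: 1-5 quality scores of one ontology at all three levels
#'
#' Integer band scores per metric, and real-valued weighted-average scores
#' per subcharacteristic and characteristic, all within `[1, 5]`.
#' Degeneracy flags are propagated from the underlying [MetricVector].
#'
#' @slot metricScores named integer vector (one per metric), each in 1..5.
#' @slot subScores named numeric vector (one per subcharacteristic).
#' @slot charScores named numeric vector (one per characteristic).
#' @slot metrics the raw [MetricVector].
#' @slot degenerate character vector of degenerate metric names.
#' @seealso [evaluateOntology()], [scoreFrame()]
#' @export
setClass("ScoreCard",
  representation(metricScores = "integer", subScores = "numeric",
                 charScores = "numeric", metrics = "MetricVector",
                 degenerate = "character")
)

setValidity("ScoreCard", function(object) {
  allScores <- c(object@metricScores, object@subScores, object@charScores)
  if (any(allScores < 1 | allScores > 5))
    return("all scores must lie in [1, 5]")
  TRUE
})

#' GeneratorSpec: parameters of the random-ontology generator
#'
#' Describes one synthetic ontology: number of classes, hierarchy shape
#' (maximum depth, parent-choice rule, multiple-parenthood probability) and
#' per-class assertion rates for properties, restrictions, annotations and
#' individuals.  Generation with a fixed seed is reproducible bit-for-bit
#' at the [OntologyGraph] level.
#'
#' @slot nClasses integer >= 1.
#' @slot maxDepth integer >= 1; maximum root-to-class depth in edges.
#' @slot branching `"uniform"` (parents drawn uniformly among eligible
#'   classes) or `"preferential"` (weight proportional to 1 + current
#'   child count, yielding broader, shallower trees).
#' @slot multiParentProb probability in `[0, 1]` that a class receives a
#'   second named parent.
#' @slot objPropRate,dataPropRate expected object/datatype property domain
#'   assertions per class (Poisson).
#' @slot restrictionRate expected anonymous restrictions per class
#'   (Poisson).
#' @slot annotationCoverage fraction of classes in `[0, 1]` carrying one
#'   `rdfs:label` annotation.
#' @slot individualsRate expected individuals per class (Poisson).
#' @slot seed integer seed, or `NA` to draw from the ambient RNG stream.
#' @seealso [generatorSpec()], [generateOntology()]
#' @export
setClass("GeneratorSpec",
  representation(
    nClasses = "integer", maxDepth = "integer", branching = "character",
    multiParentProb = "numeric", objPropRate = "numeric",
    dataPropRate = "numeric", restrictionRate = "numeric",
    annotationCoverage = "numeric", individualsRate = "numeric",
    seed = "integer"
  )
)

setValidity("GeneratorSpec", function(object) {
  msgs <- character()
  if (object@nClasses < 1L) msgs <- c(msgs, "nClasses must be >= 1")
  if (object@maxDepth < 1L)
    msgs <- c(msgs, "maxDepth must be >= 1 (depth 0 cannot host classes)")
  if (!object@branching %in% c("uniform", "preferential"))
    msgs <- c(msgs, "branching must be 'uniform' or 'preferential'")
  probs <- c(object@multiParentProb, object@annotationCoverage)
  if (any(probs < 0 | probs > 1))
    msgs <- c(msgs, "probabilities must lie in [0, 1]")
  rates <- c(object@objPropRate, object@dataPropRate,
             object@restrictionRate, object@individualsRate)
  if (any(rates < 0)) msgs <- c(msgs, "rates must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' CohortDesign: the crossed trial layout emulated by the generator
#'
#' Students are split into two groups of equal size; group A is trained on
#' three of the six topics and group B on the other three, so each topic is
#' trained for exactly one arm.  Every student produces `tasksPerTopic`
#' ontologies per topic.  The trained arm draws its ontologies from
#' effect-shifted generator parameters; per-topic gold-standard ontologies
#' are drawn from a separate spec.
#'
#' @slot students even integer (default 24).
#' @slot topics character vector of six topic codes.
#' @slot tasksPerTopic integer (default 2).
#' @slot groupATopics the three topics on which group A is trained.
#' @slot baseSpec [GeneratorSpec] for untrained-arm ontologies.
#' @slot goldSpec [GeneratorSpec] for gold-standard ontologies.
#' @slot effect named list of numeric shifts applied to `baseSpec` slots
#'   for the trained arm (e.g. `list(multiParentProb = -0.15)`), or a
#'   per-topic list of such lists named by topic.
#' @seealso [cohortDesign()], [generateCohort()]
#' @export
setClass("CohortDesign",
  representation(
    students = "integer", topics = "character", tasksPerTopic = "integer",
    groupATopics = "character", baseSpec = "GeneratorSpec",
    goldSpec = "GeneratorSpec", effect = "list"
  )
)

setValidity("CohortDesign", function(object) {
  msgs <- character()
  if (object@students < 2L || object@students %% 2L != 0L)
    msgs <- c(msgs, "students must be a positive even number")
  if (anyDuplicated(object@topics))
    msgs <- c(msgs, "topics must be unique")
  if (length(setdiff(object@groupATopics, object@topics)))
    msgs <- c(msgs, "groupATopics must be a subset of topics")
  if (length(object@groupATopics) * 2L != length(object@topics))
    msgs <- c(msgs, "each arm must be trained on half of the topics")
  if (object@tasksPerTopic < 1L)
    msgs <- c(msgs, "tasksPerTopic must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' OntologyCohort: labeled synthetic ontologies plus gold standards
#'
#' The output of [generateCohort()]: a manifest labelling every ontology
#' with (student, topic, task, arm) and the corresponding
#' [OntologyGraph] objects, together with the per-(topic, task) gold
#' standards.
#'
#' @slot manifest data.frame (`id`, `student`, `topic`, `task`, `arm`,
#'   `group`).
#' @slot graphs named list of [OntologyGraph], names matching
#'   `manifest$id`.
#' @slot goldManifest data.frame (`id`, `topic`, `task`).
#' @slot goldGraphs named list of [OntologyGraph].
#' @slot seed the master seed used.
#' @seealso [generateCohort()], [sampleBalanced()], [buildScoreTable()]
#' @export
setClass("OntologyCohort",
  representation(manifest = "data.frame", graphs = "list",
                 goldManifest = "data.frame", goldGraphs = "list",
                 seed = "integer")
)

setValidity("OntologyCohort", function(object) {
  msgs <- character()
  if (!identical(sort(object@manifest$id), sort(names(object@graphs))))
    msgs <- c(msgs, "manifest ids and graph names must match")
  if (!identical(sort(object@goldManifest$id),
                 sort(names(object@goldGraphs))))
    msgs <- c(msgs, "gold manifest ids and gold graph names must match")
  if (!all(object@manifest$arm %in% c("untrained", "trained")))
    msgs <- c(msgs, "arm must be 'untrained' or 'trained'")
  if (length(msgs)) msgs else TRUE
})
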