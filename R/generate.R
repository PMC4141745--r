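#' Construct a GeneratorSpec
#'
#' Defaults describe a small hand-built task ontology of the size a
#' student produces in a supervised modelling exercise: a shallow
#' hierarchy of a few dozen classes with sparse property, restriction and
#' annotation assertions.
#'
#' @param nClasses number of named classes (exactly honored).
#' @param maxDepth maximum root-to-class depth in edges.
#' @param branching `"uniform"` or `"preferential"` parent choice.
#' @param multiParentProb probability that a class gets a second parent.
#' @param objPropRate,dataPropRate expected object/datatype property
#'   domain assertions per class.
#' @param restrictionRate expected anonymous restrictions per class.
#' @param annotationCoverage fraction of classes carrying one
#'   `rdfs:label` annotation.
#' @param individualsRate expected individuals per class.
#' @param seed integer seed (`NA`: use the ambient RNG stream).
#' @return a validated [GeneratorSpec].
#' @export
generatorSpec <- function(nClasses = 15L, maxDepth = 4L,
                          branching = "uniform", multiParentProb = 0.15,
                          objPropRate = 0.3, dataPropRate = 0.15,
                          restrictionRate = 0.4,
                          annotationCoverage = 0.5,
                          individualsRate = 0.2, seed = NA_integer_) {
  spec <- new("GeneratorSpec", nClasses = as.integer(nClasses),
              maxDepth = as.integer(maxDepth), branching = branching,
              multiParentProb = multiParentProb,
              objPropRate = objPropRate, dataPropRate = dataPropRate,
              restrictionRate = restrictionRate,
              annotationCoverage = annotationCoverage,
              individualsRate = individualsRate,
              seed = as.integer(seed))
  validObject(spec)
  spec
}

#' Generate a random ontology from a GeneratorSpec
#'
#' Classes are attached sequentially to earlier classes (so the hierarchy
#' is acyclic by construction) subject to the depth cap; when no earlier
#' class can host a child the class becomes an additional root.  With
#' probability `multiParentProb` a class receives a second named parent.
#' Property, restriction and individual assertions are Poisson per class;
#' annotated classes carry one `rdfs:label`.  Generation is bit-for-bit
#' reproducible under a fixed seed.
#'
#' @param spec a [GeneratorSpec].
#' @param seed overrides `spec@seed` when given.
#' @return an [OntologyGraph].
#' @examples
#' g <- generateOntology(generatorSpec(nClasses = 10, seed = 7))
#' length(ontologyClasses(g))
#' @export
generateOntology <- function(spec, seed = spec@seed) {
  stopifnot(is(spec, "GeneratorSpec"))
  validObject(spec)
  n <- spec@nClasses
  base <- "http://example.org/onto"
  cls <- paste0(base, "#C", seq_len(n))

  withSeed(seed, {
    depth <- integer(n)
    edges <- list()
    childCount <- integer(n)
    for (i in seq_len(n)) {
      eligible <- which(depth[seq_len(i - 1L)] < spec@maxDepth)
      if (i == 1L || !length(eligible)) {
        depth[i] <- 1L
        next
      }
      w <- if (spec@branching == "preferential")
        1 + childCount[eligible] else rep(1, length(eligible))
      p1 <- eligible[sample.int(length(eligible), 1L, prob = w)]
      depth[i] <- depth[p1] + 1L
      childCount[p1] <- childCount[p1] + 1L
      edges[[length(edges) + 1L]] <-
        data.frame(child = cls[i], parent = cls[p1],
                   stringsAsFactors = FALSE)
      rest <- setdiff(eligible, p1)
      if (length(rest) && runif(1) < spec@multiParentProb) {
        p2 <- rest[sample.int(length(rest), 1L)]
        childCount[p2] <- childCount[p2] + 1L
        ## the recorded depth must be the longest path, or descendants
        ## could overshoot the depth cap through the deeper parent
        depth[i] <- max(depth[i], depth[p2] + 1L)
        edges[[length(edges) + 1L]] <-
          data.frame(child = cls[i], parent = cls[p2],
                     stringsAsFactors = FALSE)
      }
    }
    edges <- if (length(edges)) do.call(rbind, edges) else emptyEdges()

    doms <- list()
    for (i in seq_len(n)) {
      for (j in seq_len(rpois(1, spec@objPropRate)))
        doms[[length(doms) + 1L]] <-
          data.frame(property = sprintf("%s#op_C%d_%d", base, i, j),
                     class = cls[i], kind = "object",
                     stringsAsFactors = FALSE)
      for (j in seq_len(rpois(1, spec@dataPropRate)))
        doms[[length(doms) + 1L]] <-
          data.frame(property = sprintf("%s#dp_C%d_%d", base, i, j),
                     class = cls[i], kind = "datatype",
                     stringsAsFactors = FALSE)
    }
    doms <- if (length(doms)) do.call(rbind, doms) else emptyDomains()

    restr <- list()
    for (i in seq_len(n)) {
      for (j in seq_len(rpois(1, spec@restrictionRate))) {
        dataRestr <- runif(1) < 0.2
        type <- sample(c("some", "all", "min", "exact"), 1L)
        filler <- if (type %in% c("min", "exact")) {
          as.character(sample.int(3L, 1L))
        } else if (dataRestr) {
          paste0(NS_XSD, "string")
        } else {
          cls[sample.int(n, 1L)]
        }
        restr[[length(restr) + 1L]] <- data.frame(
          class = cls[i],
          property = sprintf("%s#%s_C%d_%d", base,
                             if (dataRestr) "rdp" else "rop", i, j),
          kind = if (dataRestr) "datatype" else "object",
          type = type, filler = filler,
          axiom = sample(c("subclass", "equivalent"), 1L,
                         prob = c(0.8, 0.2)),
          stringsAsFactors = FALSE)
      }
    }
    restr <- if (length(restr)) do.call(rbind, restr)
             else emptyRestrictions()

    annotated <- runif(n) < spec@annotationCoverage
    annos <- if (any(annotated)) data.frame(
      class = cls[annotated],
      property = paste0(NS_RDFS, "label"),
      value = paste("label for", sub(".*#", "", cls[annotated])),
      stringsAsFactors = FALSE) else emptyAnnotations()

    indiv <- list()
    for (i in seq_len(n)) {
      for (j in seq_len(rpois(1, spec@individualsRate)))
        indiv[[length(indiv) + 1L]] <-
          data.frame(individual = sprintf("%s#ind_C%d_%d", base, i, j),
                     class = cls[i], stringsAsFactors = FALSE)
    }
    indiv <- if (length(indiv)) do.call(rbind, indiv)
             else emptyIndividuals()

    new("OntologyGraph", classes = cls, edges = edges,
        thingChildren = character(), propertyDomains = doms,
        restrictions = restr, individuals = indiv, annotations = annos,
        ontologyIRI = base)
  })
}
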