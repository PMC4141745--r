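#' Parse an OWL 2 RDF/XML document into an OntologyGraph
#'
#' Reads the asserted content of an OWL ontology serialized as RDF/XML and
#' builds the metric-oriented [OntologyGraph] model.  Only the document's
#' own axioms are read: `owl:imports` are never resolved, no reasoning is
#' performed, and anonymous class expressions are never counted as
#' classes.  Exact duplicate axioms are collapsed to a single occurrence.
#'
#' Conventions:
#' * named classes are `owl:Class` nodes (or `rdf:Description` nodes typed
#'   `owl:Class`) carrying `rdf:about` or `rdf:ID`, plus any named class
#'   referenced as a superclass;
#' * `rdfs:subClassOf` with a named object becomes a subclass edge; an
#'   asserted parent of `owl:Thing` is recorded separately and excluded
#'   from metric edge totals;
#' * anonymous `owl:Restriction` expressions reached through
#'   `rdfs:subClassOf` or `owl:equivalentClass` are tallied per class (an
#'   equivalence axiom contributes its restriction operands but no
#'   subclass edge), each occurrence also counting as a property usage;
#' * property domain declarations on declared object/datatype properties
#'   are tallied per class;
#' * individuals are `rdf:type` class-membership assertions; annotations
#'   are assertions on a class subject whose property is `rdfs:label`,
#'   `rdfs:comment`, `rdfs:seeAlso`, `rdfs:isDefinedBy`,
#'   `owl:versionInfo`, or any property the document declares as an
#'   `owl:AnnotationProperty`.
#'
#' @param source path, URL, raw vector or literal XML string accepted by
#'   [xml2::read_xml()].
#' @param restrictionTypes which restriction constructors to count; the
#'   default is the inclusive convention (existential, universal,
#'   cardinality and value restrictions).
#' @return an [OntologyGraph].  A well-formed document declaring zero
#'   classes yields a valid empty graph.
#' @examples
#' doc <- '<?xml version="1.0"?>
#' <rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
#'          xmlns:owl="http://www.w3.org/2002/07/owl#">
#'   <owl:Class rdf:about="http://example.org/onto#A"/>
#' </rdf:RDF>'
#' g <- parseOWL(doc)
#' ontologyClasses(g)
#' @export
parseOWL <- function(source,
                     restrictionTypes = c("some", "all", "min", "max",
                                          "exact", "hasValue")) {
  restrictionTypes <- match.arg(restrictionTypes, several.ok = TRUE)
  doc <- tryCatch(
    xml2::read_xml(source),
    error = function(e)
      stop("OWL parse error: ", conditionMessage(e), call. = FALSE)
  )
  ns <- c(rdf = NS_RDF, rdfs = NS_RDFS, owl = NS_OWL)
  if (!identical(xml2::xml_name(doc, ns), "rdf:RDF"))
    stop("OWL parse error: document root is not rdf:RDF", call. = FALSE)
  base <- xml2::xml_attr(doc, "base")
  if (is.na(base)) base <- ""
  nsAll <- xml2::xml_ns(doc)

  resolveRef <- function(iri) {
    if (is.na(iri)) return(NA_character_)
    if (startsWith(iri, "#")) paste0(base, iri) else iri
  }
  nodeAbout <- function(node) {
    about <- xml2::xml_attr(node, "about")
    if (!is.na(about)) return(resolveRef(about))
    id <- xml2::xml_attr(node, "ID")
    if (!is.na(id)) return(paste0(base, "#", id))
    NA_character_
  }
  nodeIRI <- function(node) {
    nm <- xml2::xml_name(node, nsAll)
    if (!grepl(":", nm, fixed = TRUE)) return(nm)
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    uri <- nsAll[[parts[1]]]
    if (is.null(uri)) parts[2] else paste0(uri, parts[2])
  }

  ## -- entity declarations ------------------------------------------------
  classNodes <- xml2::xml_find_all(doc, ".//owl:Class", ns)
  descrNodes <- xml2::xml_find_all(
    doc, sprintf(".//rdf:Description[rdf:type/@rdf:resource='%sClass']",
                 NS_OWL), ns)
  classNodes <- c(classNodes, descrNodes)
  classIRIs <- vapply(classNodes, nodeAbout, character(1))
  keep <- !is.na(classIRIs) & classIRIs != OWL_THING
  classNodes <- classNodes[keep]
  classIRIs <- classIRIs[keep]

  propKind <- character()
  for (tag in c(object = "ObjectProperty", datatype = "DatatypeProperty",
                annotation = "AnnotationProperty")) {
    nodes <- xml2::xml_find_all(doc, paste0(".//owl:", tag), ns)
    iris <- vapply(nodes, nodeAbout, character(1))
    iris <- iris[!is.na(iris)]
    kindName <- names(which(c(object = "ObjectProperty",
                              datatype = "DatatypeProperty",
                              annotation = "AnnotationProperty") == tag))
    propKind[iris] <- kindName
  }
  annotationProps <- c(STD_ANNOTATION_PROPS,
                       names(propKind)[propKind == "annotation"])

  ## -- per-class axioms ---------------------------------------------------
  edges <- list(); thingKids <- character(); restr <- list(); annos <- list()

  parseRestriction <- function(rnode, classIRI, axiom) {
    propNode <- xml2::xml_find_first(rnode, "./owl:onProperty", ns)
    prop <- NA_character_
    if (!inherits(propNode, "xml_missing")) {
      prop <- resolveRef(xml2::xml_attr(propNode, "resource"))
      if (is.na(prop)) {
        inner <- xml2::xml_find_first(propNode, "./*")
        if (!inherits(inner, "xml_missing")) prop <- nodeAbout(inner)
      }
    }
    spec <- list(
      some = "./owl:someValuesFrom", all = "./owl:allValuesFrom",
      min = "./owl:minCardinality | ./owl:minQualifiedCardinality",
      max = "./owl:maxCardinality | ./owl:maxQualifiedCardinality",
      exact = "./owl:cardinality | ./owl:qualifiedCardinality",
      hasValue = "./owl:hasValue")
    type <- NA_character_; filler <- NA_character_
    for (ty in names(spec)) {
      hit <- xml2::xml_find_first(rnode, spec[[ty]], ns)
      if (!inherits(hit, "xml_missing")) {
        type <- ty
        filler <- resolveRef(xml2::xml_attr(hit, "resource"))
        if (is.na(filler)) {
          inner <- xml2::xml_find_first(hit, "./*")
          filler <- if (!inherits(inner, "xml_missing")) nodeAbout(inner)
                    else xml2::xml_text(hit)
        }
        break
      }
    }
    if (is.na(type) || !(type %in% restrictionTypes)) return(NULL)
    kind <- if (!is.na(prop) && prop %in% names(propKind) &&
                propKind[[prop]] %in% c("object", "datatype"))
      propKind[[prop]]
    else if (!is.na(filler) && startsWith(filler, NS_XSD)) "datatype"
    else "object"
    data.frame(class = classIRI, property = prop, kind = kind, type = type,
               filler = filler, axiom = axiom, stringsAsFactors = FALSE)
  }

  for (i in seq_along(classNodes)) {
    node <- classNodes[[i]]
    iri <- classIRIs[[i]]
    for (sub in xml2::xml_find_all(node, "./rdfs:subClassOf", ns)) {
      parent <- resolveRef(xml2::xml_attr(sub, "resource"))
      if (is.na(parent)) {
        named <- xml2::xml_find_first(sub, "./owl:Class", ns)
        if (!inherits(named, "xml_missing")) parent <- nodeAbout(named)
      }
      if (!is.na(parent)) {
        if (parent == OWL_THING) thingKids <- c(thingKids, iri)
        else if (parent == iri)
          warning("dropping self subclass edge on ", iri, call. = FALSE)
        else edges[[length(edges) + 1L]] <-
          data.frame(child = iri, parent = parent,
                     stringsAsFactors = FALSE)
      }
      for (rnode in xml2::xml_find_all(sub, ".//owl:Restriction", ns))
        restr[[length(restr) + 1L]] <-
          parseRestriction(rnode, iri, "subclass")
    }
    for (eq in xml2::xml_find_all(node, "./owl:equivalentClass", ns)) {
      for (rnode in xml2::xml_find_all(eq, ".//owl:Restriction", ns))
        restr[[length(restr) + 1L]] <-
          parseRestriction(rnode, iri, "equivalent")
    }
    for (child in xml2::xml_children(node)) {
      if (nodeIRI(child) %in% annotationProps) {
        val <- resolveRef(xml2::xml_attr(child, "resource"))
        if (is.na(val)) val <- xml2::xml_text(child)
        annos[[length(annos) + 1L]] <-
          data.frame(class = iri, property = nodeIRI(child), value = val,
                     stringsAsFactors = FALSE)
      }
    }
  }

  edges <- if (length(edges)) unique(do.call(rbind, edges))
           else emptyEdges()
  restr <- restr[!vapply(restr, is.null, logical(1))]
  restr <- if (length(restr)) unique(do.call(rbind, restr))
           else emptyRestrictions()
  annos <- if (length(annos)) unique(do.call(rbind, annos))
           else emptyAnnotations()

  ## named superclasses referenced but never declared still count as
  ## classes (edge endpoints must be members of the class set)
  classes <- unique(c(classIRIs, edges$parent))
  thingKids <- unique(thingKids)
  restr <- restr[restr$class %in% classes, , drop = FALSE]
  annos <- annos[annos$class %in% classes, , drop = FALSE]

  ## -- property domain declarations --------------------------------------
  doms <- list()
  for (tag in c(object = "ObjectProperty", datatype = "DatatypeProperty")) {
    kindName <- if (tag == "ObjectProperty") "object" else "datatype"
    for (pnode in xml2::xml_find_all(doc, paste0(".//owl:", tag), ns)) {
      prop <- nodeAbout(pnode)
      if (is.na(prop)) next
      for (d in xml2::xml_find_all(pnode, "./rdfs:domain", ns)) {
        cls <- resolveRef(xml2::xml_attr(d, "resource"))
        if (!is.na(cls) && cls %in% classes)
          doms[[length(doms) + 1L]] <-
            data.frame(property = prop, class = cls, kind = kindName,
                       stringsAsFactors = FALSE)
      }
    }
  }
  doms <- if (length(doms)) unique(do.call(rbind, doms))
          else emptyDomains()

  ## -- individuals --------------------------------------------------------
  indivNodes <- c(
    xml2::xml_find_all(doc, ".//owl:NamedIndividual", ns),
    xml2::xml_find_all(doc, ".//rdf:Description[rdf:type]", ns)
  )
  indiv <- list()
  for (inode in indivNodes) {
    ind <- nodeAbout(inode)
    if (is.na(ind)) next
    for (ty in xml2::xml_find_all(inode, "./rdf:type", ns)) {
      cls <- resolveRef(xml2::xml_attr(ty, "resource"))
      if (!is.na(cls) && cls %in% classes)
        indiv[[length(indiv) + 1L]] <-
          data.frame(individual = ind, class = cls,
                     stringsAsFactors = FALSE)
    }
  }
  indiv <- if (length(indiv)) unique(do.call(rbind, indiv))
           else emptyIndividuals()

  ontoNode <- xml2::xml_find_first(doc, "./owl:Ontology", ns)
  ontoIRI <- if (inherits(ontoNode, "xml_missing")) NA_character_
             else nodeAbout(ontoNode)

  new("OntologyGraph", classes = classes, edges = edges,
      thingChildren = thingKids, propertyDomains = doms,
      restrictions = restr, individuals = indiv, annotations = annos,
      ontologyIRI = ontoIRI)
}
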