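#' Serialize an OntologyGraph as OWL 2 RDF/XML
#'
#' Writes a deterministic RDF/XML document (stable byte output for a
#' given graph): property declarations with their domain assertions,
#' class declarations with subclass axioms, restriction expressions,
#' annotations, and individuals with membership assertions.
#' `parseOWL(writeOWL(g))` reproduces every assertion table of `g`.
#'
#' @param g an [OntologyGraph].
#' @param path output file path, or `NULL` to return the document as a
#'   single character string.
#' @return `path` invisibly, or the XML text when `path = NULL`.
#' @seealso [parseOWL()]
#' @export
writeOWL <- function(g, path = NULL) {
  stopifnot(is(g, "OntologyGraph"))
  esc <- xmlEscape
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<rdf:RDF xmlns:rdf="', NS_RDF, '"'),
    paste0('         xmlns:rdfs="', NS_RDFS, '"'),
    paste0('         xmlns:owl="', NS_OWL, '"'),
    paste0('         xmlns:xsd="', NS_XSD, '">')
  )
  if (!is.na(g@ontologyIRI))
    out <- c(out, sprintf('  <owl:Ontology rdf:about="%s"/>',
                          esc(g@ontologyIRI)))

  ## non-standard annotation properties need a declaration so a reader
  ## can recognize them as annotations
  customAnn <- setdiff(unique(g@annotations$property),
                       STD_ANNOTATION_PROPS)
  out <- c(out, sprintf('  <owl:AnnotationProperty rdf:about="%s"/>',
                        esc(sort(customAnn))))

  ## property declarations: domain-carrying plus restriction properties
  props <- unique(rbind(
    g@propertyDomains[, c("property", "kind")],
    g@restrictions[!is.na(g@restrictions$property),
                   c("property", "kind")]
  ))
  props <- props[order(props$property), , drop = FALSE]
  for (i in seq_len(nrow(props))) {
    tag <- if (props$kind[i] == "datatype") "owl:DatatypeProperty"
           else "owl:ObjectProperty"
    doms <- g@propertyDomains$class[
      g@propertyDomains$property == props$property[i]]
    if (length(doms)) {
      out <- c(out, sprintf('  <%s rdf:about="%s">', tag,
                            esc(props$property[i])),
               sprintf('    <rdfs:domain rdf:resource="%s"/>', esc(doms)),
               sprintf('  </%s>', tag))
    } else {
      out <- c(out, sprintf('  <%s rdf:about="%s"/>', tag,
                            esc(props$property[i])))
    }
  }

  restrictionXML <- function(r, indent) {
    pad <- strrep(" ", indent)
    fillerLine <- switch(r$type,
      some = sprintf('%s  <owl:someValuesFrom rdf:resource="%s"/>',
                     pad, esc(r$filler)),
      all = sprintf('%s  <owl:allValuesFrom rdf:resource="%s"/>',
                    pad, esc(r$filler)),
      min = sprintf(paste0('%s  <owl:minCardinality rdf:datatype=',
                           '"%snonNegativeInteger">%s</owl:minCardinality>'),
                    pad, NS_XSD, esc(r$filler)),
      max = sprintf(paste0('%s  <owl:maxCardinality rdf:datatype=',
                           '"%snonNegativeInteger">%s</owl:maxCardinality>'),
                    pad, NS_XSD, esc(r$filler)),
      exact = sprintf(paste0('%s  <owl:cardinality rdf:datatype=',
                             '"%snonNegativeInteger">%s</owl:cardinality>'),
                      pad, NS_XSD, esc(r$filler)),
      hasValue = sprintf('%s  <owl:hasValue rdf:resource="%s"/>',
                         pad, esc(r$filler))
    )
    c(sprintf('%s<owl:Restriction>', pad),
      sprintf('%s  <owl:onProperty rdf:resource="%s"/>', pad,
              esc(r$property)),
      fillerLine,
      sprintf('%s</owl:Restriction>', pad))
  }

  for (cls in g@classes) {
    body <- character()
    parents <- g@edges$parent[g@edges$child == cls]
    body <- c(body,
              sprintf('    <rdfs:subClassOf rdf:resource="%s"/>',
                      esc(parents)))
    if (cls %in% g@thingChildren)
      body <- c(body, sprintf('    <rdfs:subClassOf rdf:resource="%s"/>',
                              OWL_THING))
    rs <- g@restrictions[g@restrictions$class == cls, , drop = FALSE]
    for (j in seq_len(nrow(rs))) {
      wrap <- if (rs$axiom[j] == "equivalent") "owl:equivalentClass"
              else "rdfs:subClassOf"
      body <- c(body, sprintf('    <%s>', wrap),
                restrictionXML(rs[j, ], 6L),
                sprintf('    </%s>', wrap))
    }
    an <- g@annotations[g@annotations$class == cls, , drop = FALSE]
    for (j in seq_len(nrow(an))) {
      prop <- an$property[j]
      qname <- if (startsWith(prop, NS_RDFS))
        paste0("rdfs:", substring(prop, nchar(NS_RDFS) + 1L))
      else if (startsWith(prop, NS_OWL))
        paste0("owl:", substring(prop, nchar(NS_OWL) + 1L))
      else NA_character_
      if (is.na(qname)) {
        ## arbitrary annotation IRIs get a one-off namespace binding
        nsPart <- sub("[^/#]*$", "", prop)
        local <- substring(prop, nchar(nsPart) + 1L)
        body <- c(body,
                  sprintf('    <ann:%s xmlns:ann="%s">%s</ann:%s>',
                          local, esc(nsPart), esc(an$value[j]), local))
      } else {
        body <- c(body, sprintf('    <%s>%s</%s>', qname,
                                esc(an$value[j]), qname))
      }
    }
    if (length(body)) {
      out <- c(out, sprintf('  <owl:Class rdf:about="%s">', esc(cls)),
               body, '  </owl:Class>')
    } else {
      out <- c(out, sprintf('  <owl:Class rdf:about="%s"/>', esc(cls)))
    }
  }

  for (ind in unique(g@individuals$individual)) {
    types <- g@individuals$class[g@individuals$individual == ind]
    out <- c(out,
             sprintf('  <owl:NamedIndividual rdf:about="%s">', esc(ind)),
             sprintf('    <rdf:type rdf:resource="%s"/>', esc(types)),
             '  </owl:NamedIndividual>')
  }

  out <- c(out, '</rdf:RDF>', '')
  text <- paste(out, collapse = "\n")
  if (is.null(path)) return(text)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(text), con)
  invisible(path)
}
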