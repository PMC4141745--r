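## Hand-built graphs used across tests; constructed directly so the
## assertions do not depend on the parser.

owlThing <- function() "http://www.w3.org/2002/07/owl#Thing"

iri <- function(x) {
  if (!length(x)) return(character(0))  # paste0 would recycle to ""
  paste0("http://example.org/fix#", x)
}

makeGraph <- function(classes, edges = NULL, thingChildren = character(),
                      domains = NULL, restrictions = NULL,
                      individuals = NULL, annotations = NULL) {
  df <- function(x, proto) if (is.null(x)) proto else x
  new("OntologyGraph",
      classes = iri(classes),
      edges = if (is.null(edges))
        data.frame(child = character(), parent = character(),
                   stringsAsFactors = FALSE)
      else data.frame(child = iri(edges$child), parent = iri(edges$parent),
                      stringsAsFactors = FALSE),
      thingChildren = if (length(thingChildren)) iri(thingChildren)
                      else character(),
      propertyDomains = df(domains, data.frame(
        property = character(), class = character(), kind = character(),
        stringsAsFactors = FALSE)),
      restrictions = df(restrictions, data.frame(
        class = character(), property = character(), kind = character(),
        type = character(), filler = character(), axiom = character(),
        stringsAsFactors = FALSE)),
      individuals = df(individuals, data.frame(
        individual = character(), class = character(),
        stringsAsFactors = FALSE)),
      annotations = df(annotations, data.frame(
        class = character(), property = character(), value = character(),
        stringsAsFactors = FALSE)),
      ontologyIRI = NA_character_)
}

chainGraph <- function() {
  makeGraph(c("A", "B", "C"),
            edges = data.frame(child = c("B", "C"), parent = c("A", "B")))
}

diamondGraph <- function() {
  makeGraph(c("A", "B", "C", "D"),
            edges = data.frame(child = c("B", "C", "D", "D"),
                               parent = c("A", "A", "B", "C")))
}

fixturePath <- function(name) {
  system.file("extdata", name, package = "oquare", mustWork = TRUE)
}
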