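minimalDoc <- function(body = "") {
  paste0('<?xml version="1.0"?>\n',
         '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"\n',
         '         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"\n',
         '         xmlns:owl="http://www.w3.org/2002/07/owl#">\n',
         body, '\n</rdf:RDF>')
}

test_that("a document with a single class yields a graph with no assertions", {
  g <- parseOWL(minimalDoc('<owl:Class rdf:about="http://x.org/o#A"/>'))
  expect_identical(ontologyClasses(g), "http://x.org/o#A")
  expect_identical(nrow(subclassEdges(g)), 0L)
  expect_identical(propertyAssertions(g), 0L)
  expect_identical(restrictionAssertions(g), 0L)
  expect_identical(individualAssertions(g), 0L)
  expect_identical(annotationAssertions(g), 0L)
})

test_that("a well-formed document with zero classes is a valid empty graph", {
  g <- parseOWL(minimalDoc(""))
  expect_s4_class(g, "OntologyGraph")
  expect_length(ontologyClasses(g), 0)
})

test_that("the chain fixture parses to 3 classes and 2 asserted edges", {
  g <- parseOWL(fixturePath("chain3.owl"))
  expect_setequal(sub(".*#", "", ontologyClasses(g)), c("A", "B", "C"))
  e <- subclassEdges(g)
  expect_identical(nrow(e), 2L)
  expect_setequal(paste(sub(".*#", "", e$child), sub(".*#", "", e$parent)),
                  c("B A", "C B"))
})

test_that("malformed XML raises a parse error", {
  suppressWarnings(
    expect_error(parseOWL("<rdf:RDF><owl:Class"), "parse error"))
  expect_error(parseOWL(minimalDoc("<unclosed>")), "parse error")
  expect_error(parseOWL('<?xml version="1.0"?><notRDF/>'), "rdf:RDF")
})

test_that("parsing is deterministic: same bytes give identical graphs", {
  doc <- writeOWL(generateOntology(generatorSpec(nClasses = 25, seed = 11)))
  expect_identical(parseOWL(doc), parseOWL(doc))
})

test_that("duplicate axioms are counted once", {
  body <- paste0(
    '<owl:Class rdf:about="http://x.org/o#A"/>',
    '<owl:Class rdf:about="http://x.org/o#B">',
    '<rdfs:subClassOf rdf:resource="http://x.org/o#A"/>',
    '<rdfs:subClassOf rdf:resource="http://x.org/o#A"/>',
    '<rdfs:label>b</rdfs:label><rdfs:label>b</rdfs:label>',
    '</owl:Class>')
  g <- parseOWL(minimalDoc(body))
  expect_identical(nrow(subclassEdges(g)), 1L)
  expect_identical(annotationAssertions(g), 1L)
})

test_that("asserted owl:Thing parents are recorded but are not metric edges", {
  body <- paste0(
    '<owl:Class rdf:about="http://x.org/o#A">',
    '<rdfs:subClassOf rdf:resource=',
    '"http://www.w3.org/2002/07/owl#Thing"/></owl:Class>',
    '<owl:Class rdf:about="http://x.org/o#B">',
    '<rdfs:subClassOf rdf:resource="http://x.org/o#A"/></owl:Class>')
  g <- parseOWL(minimalDoc(body))
  expect_identical(nrow(subclassEdges(g)), 1L)
  expect_identical(g@thingChildren, "http://x.org/o#A")
  expect_length(rootToLeafPaths(g), 1)
})

test_that("equivalence axioms contribute restrictions but no subclass edges", {
  body <- paste0(
    '<owl:ObjectProperty rdf:about="http://x.org/o#p"/>',
    '<owl:Class rdf:about="http://x.org/o#A">',
    '<owl:equivalentClass><owl:Restriction>',
    '<owl:onProperty rdf:resource="http://x.org/o#p"/>',
    '<owl:someValuesFrom rdf:resource="http://x.org/o#A"/>',
    '</owl:Restriction></owl:equivalentClass></owl:Class>')
  g <- parseOWL(minimalDoc(body))
  expect_identical(nrow(subclassEdges(g)), 0L)
  expect_identical(restrictionAssertions(g), 1L)
  expect_identical(propertyAssertions(g, "object"), 1L)
  expect_identical(g@restrictions$axiom, "equivalent")
})

test_that("path enumeration matches hand-derived examples", {
  # chain Thing -> A -> B -> C: one path of 3 edges
  p <- rootToLeafPaths(chainGraph())
  expect_length(p, 1)
  expect_identical(lengths(p) - 1L, 3L)  # first element is owl:Thing
  # diamond: two paths to D, each of length 3
  p <- rootToLeafPaths(diamondGraph())
  expect_length(p, 2)
  expect_true(all(lengths(p) - 1L == 3L))
  # single orphan class: Thing -> A, length 1
  p <- rootToLeafPaths(makeGraph("A"))
  expect_length(p, 1)
  expect_identical(lengths(p) - 1L, 1L)
})

test_that("cycles in the subclass hierarchy are rejected with a cycle report", {
  g <- makeGraph(c("A", "B"),
                 edges = data.frame(child = c("A", "B"),
                                    parent = c("B", "A")))
  expect_error(rootToLeafPaths(g), "cycle")
  expect_error(computeMetrics(g), "cycle")
})

test_that("path enumeration agrees with a brute-force oracle on random DAGs", {
  for (seed in 1:25) {
    g <- generateOntology(randomSpec(seed))
    got <- sort(lengths(rootToLeafPaths(g)) - 1L)
    want <- sort(lengths(oraclePaths(g)))
    expect_identical(got, as.integer(want), label = paste("seed", seed))
  }
})

test_that("per-class tallies sum to the totals", {
  g <- generateOntology(generatorSpec(nClasses = 30, seed = 4))
  for (f in list(propertyAssertions, restrictionAssertions,
                 individualAssertions, annotationAssertions)) {
    expect_identical(sum(f(g, perClass = TRUE)), f(g))
  }
})

test_that("OntologyGraph validity rejects malformed content", {
  expect_error(makeGraph("A", edges = data.frame(child = "A",
                                                 parent = "A")),
               "child == parent")
  expect_error(makeGraph("A", edges = data.frame(child = "A",
                                                 parent = "Z")),
               "not in classes")
})
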