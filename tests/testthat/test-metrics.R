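test_that("chain fixture metrics match hand enumeration", {
  v <- metricValues(computeMetrics(chainGraph()))
  expect_equal(v[["DITOnto"]], 3)
  expect_equal(v[["LCOMOnto"]], 3)
  expect_equal(v[["NACOnto"]], 1)
  expect_equal(v[["INROnto"]], 2 / 3)
  expect_equal(v[["PROnto"]], 0)
  expect_equal(v[["ANOnto"]], 0)
  expect_equal(v[["NOCOnto"]], 1)  # 2 edges / 2 classes with a parent
})

test_that("diamond fixture metrics match hand enumeration", {
  v <- metricValues(computeMetrics(diamondGraph()))
  expect_equal(v[["DITOnto"]], 3)
  expect_equal(v[["LCOMOnto"]], 3)
  expect_equal(v[["NACOnto"]], 2)
  expect_equal(v[["INROnto"]], 1)
  expect_equal(v[["NOCOnto"]], 4 / 3)
})

test_that("a single orphan class has depth 1 and zero averages", {
  mv <- computeMetrics(makeGraph("A"))
  v <- metricValues(mv)
  expect_equal(v[["DITOnto"]], 1)
  expect_equal(v[["LCOMOnto"]], 1)
  expect_equal(v[["NACOnto"]], 1)  # implicit root attachment
  expect_equal(unname(v[c("WMCOnto", "NOMOnto", "RFCOnto", "PROnto",
                          "AROnto", "INROnto", "CROnto", "ANOnto")]),
               rep(0, 8))
  expect_setequal(degenerateMetrics(mv), c("NOCOnto", "PROnto"))
})

test_that("annotation and individual averages divide by the class count", {
  g <- makeGraph(c("A", "B"),
    annotations = data.frame(class = iri(c("A", "A", "B")),
                             property = rep("p", 3),
                             value = c("x", "y", "z"),
                             stringsAsFactors = FALSE),
    individuals = data.frame(individual = paste0("i", 1:4),
                             class = iri(c("A", "A", "B", "B")),
                             stringsAsFactors = FALSE))
  v <- metricValues(computeMetrics(g))
  expect_equal(v[["ANOnto"]], 1.5)
  expect_equal(v[["CROnto"]], 2.0)
})

test_that("the empty graph is fully degenerate and reports zeros", {
  mv <- computeMetrics(makeGraph(character()))
  expect_true(all(metricValues(mv) == 0))
  expect_setequal(degenerateMetrics(mv), metricNames())
})

test_that("all 12 metrics agree with the brute-force oracle on random DAGs", {
  for (seed in 101:140) {
    g <- generateOntology(randomSpec(seed))
    got <- metricValues(computeMetrics(g))
    want <- oracleMetrics(g)
    expect_equal(got[names(want)], want, tolerance = 1e-12,
                 label = paste("seed", seed))
  }
})

test_that("metric invariants hold on random graphs", {
  for (seed in 201:230) {
    g <- generateOntology(randomSpec(seed))
    v <- metricValues(computeMetrics(g))
    expect_true(all(v >= 0))
    expect_lte(v[["LCOMOnto"]], v[["DITOnto"]])
    expect_gte(v[["PROnto"]], 0); expect_lte(v[["PROnto"]], 1)
    # conservation: INROnto * |classes| == subclass-edge total
    expect_equal(v[["INROnto"]] * length(ontologyClasses(g)),
                 nrow(subclassEdges(g)), tolerance = 1e-12)
  }
})

test_that("an ontology with no properties has the no-property identities", {
  g <- chainGraph()
  v <- metricValues(computeMetrics(g))
  expect_equal(v[["NOMOnto"]], 0)
  expect_equal(v[["RFCOnto"]], 0)
  expect_equal(v[["PROnto"]], 0)
  expect_equal(v[["WMCOnto"]] - v[["INROnto"]], 0, tolerance = 1e-12)
})

test_that("duplicating a structure as two disjoint copies keeps averages", {
  g1 <- generateOntology(generatorSpec(nClasses = 12, seed = 9))
  ## second disjoint copy under the root: same tables with renamed IRIs
  rename <- function(x) sub("#", "#copy_", x)
  renameTab <- function(tab) {
    for (cl in intersect(c("child", "parent", "class", "property",
                           "individual", "filler"), names(tab))) {
      hit <- grepl("^http://example.org/onto#", tab[[cl]])
      tab[[cl]][hit] <- rename(tab[[cl]][hit])
    }
    tab
  }
  g2 <- new("OntologyGraph",
            classes = c(g1@classes, rename(g1@classes)),
            edges = rbind(g1@edges, renameTab(g1@edges)),
            thingChildren = character(),
            propertyDomains = rbind(g1@propertyDomains,
                                    renameTab(g1@propertyDomains)),
            restrictions = rbind(g1@restrictions,
                                 renameTab(g1@restrictions)),
            individuals = rbind(g1@individuals, renameTab(g1@individuals)),
            annotations = rbind(g1@annotations, renameTab(g1@annotations)),
            ontologyIRI = NA_character_)
  v1 <- metricValues(computeMetrics(g1))
  v2 <- metricValues(computeMetrics(g2))
  perClass <- c("WMCOnto", "NACOnto", "NOCOnto", "RFCOnto", "NOMOnto",
                "PROnto", "AROnto", "INROnto", "CROnto", "ANOnto",
                "DITOnto")
  expect_equal(v2[perClass], v1[perClass], tolerance = 1e-12)
})

test_that("adding one annotation raises ANOnto and changes nothing else", {
  g <- generateOntology(generatorSpec(nClasses = 10, seed = 2))
  g2 <- g
  g2@annotations <- rbind(g2@annotations, data.frame(
    class = g@classes[1], property = "http://x.org/newAnn", value = "v",
    stringsAsFactors = FALSE))
  v1 <- metricValues(computeMetrics(g))
  v2 <- metricValues(computeMetrics(g2))
  expect_gt(v2[["ANOnto"]], v1[["ANOnto"]])
  others <- setdiff(metricNames(), "ANOnto")
  expect_equal(v2[others], v1[others], tolerance = 1e-15)
})

test_that("rfcInherited counts ancestor-attached property assertions", {
  ## A <- B: property on A; directly B reaches 0, with inheritance 1
  g <- makeGraph(c("A", "B"),
                 edges = data.frame(child = "B", parent = "A"),
                 domains = data.frame(property = "p", class = iri("A"),
                                      kind = "object",
                                      stringsAsFactors = FALSE))
  direct <- metricValues(computeMetrics(g))[["RFCOnto"]]
  inh <- metricValues(computeMetrics(g, rfcInherited = TRUE))[["RFCOnto"]]
  expect_equal(direct, 0.5)   # 1 assertion / 2 classes
  expect_equal(inh, 1.0)      # A reaches 1, B inherits 1
})
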