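test_that("band lookup maps values to 1-5 with half-open boundaries", {
  bands <- c(0.2, 0.4, 0.6, 0.8)
  expect_identical(scoreMetric(0.5, "higher", bands), 3L)
  expect_identical(scoreMetric(0.1, "lower", bands), 5L)
  expect_identical(scoreMetric(0.6, "higher", bands), 4L)  # at b3
  expect_identical(scoreMetric(0.0, "higher", bands), 1L)
  expect_identical(scoreMetric(0.9, "higher", bands), 5L)
  expect_identical(scoreMetric(0.9, "lower", bands), 1L)
  # monotone over a grid
  s <- scoreMetric(seq(0, 1, by = 0.01), "higher", bands)
  expect_true(all(diff(s) >= 0))
  expect_error(scoreMetric(NaN, "higher", bands), "non-finite")
  expect_error(scoreMetric(1, "higher", c(1, 1, 2, 3)), "increasing")
})

test_that("weighted aggregation behaves as a weighted mean", {
  expect_equal(scoreAggregate(c(4, 2), c(0.5, 0.5)), 3)
  expect_equal(scoreAggregate(c(4, 2), c(1, 0)), 4)
  expect_equal(scoreAggregate(c(5, 5, 5), c(0.2, 0.5, 0.3)), 5)
  expect_equal(scoreAggregate(c(3, 5), c(0.5, 0.5)), 4)
  expect_equal(scoreAggregate(2.5, 1), 2.5)   # identity
  expect_equal(scoreAggregate(c(1, 1, 1), c(1, 2, 3)), 1)
  expect_error(scoreAggregate(c(1, 2), c(0, 0)), "positive sum")
  # bounded by min/max of inputs on random draws
  for (i in 1:20) {
    s <- runif(4, 1, 5); w <- runif(4)
    agg <- scoreAggregate(s, w)
    expect_gte(agg, min(s)); expect_lte(agg, max(s))
  }
})

test_that("the default model has the full 29/7 roster and valid structure", {
  model <- defaultQualityModel()
  expect_identical(sort(subcharacteristicNames(model)), sort(c(
    "Reference Ontology", "Text Analysis", "Infering", "Formalisation",
    "Formal Relation Support", "Consistency",
    "Schema And Value Reconciliation", "Indexing And Linking",
    "Clustering And Similarity", "Guidance And Decision Trees",
    "Results Representation", "Knowledge Reuse", "Tangledness",
    "Modularity", "Knowledge Acquisition", "Modification Stability",
    "Learnability", "Reusability", "Changeability", "Availability",
    "Cohesion", "Analysability", "Testability", "Adaptability",
    "Consistent Search And Query", "Replaceability", "Recoverability",
    "Controlled Vocabulary", "Redundancy")))
  expect_identical(sort(characteristicNames(model)), sort(c(
    "Structural", "Functional Adequacy", "Compatibility", "Operability",
    "Reliability", "Maintainability", "Transferability")))
  # every metric feeds at least one subcharacteristic; ANOnto feeds
  # several (annotation richness supports reuse and redundancy)
  used <- unique(unlist(lapply(model@subcharacteristics, names)))
  expect_setequal(used, metricNames())
  feedsANOnto <- names(Filter(function(w) "ANOnto" %in% names(w),
                              model@subcharacteristics))
  expect_true(all(c("Knowledge Reuse", "Redundancy") %in% feedsANOnto))
  # weights normalized
  expect_true(all(vapply(model@subcharacteristics, sum, 1) - 1 < 1e-12))
})

test_that("evaluateOntology emits all three levels within [1,5]", {
  card <- evaluateOntology(generateOntology(generatorSpec(nClasses = 20,
                                                          seed = 5)))
  expect_length(metricScores(card), 12)
  expect_length(subcharacteristicScores(card), 29)
  expect_length(characteristicScores(card), 7)
  sf <- scoreFrame(card)
  expect_identical(nrow(sf), 48L)
  expect_true(all(sf$score >= 1 & sf$score <= 5))
})

test_that("identical ontologies yield identical score cards", {
  g1 <- generateOntology(generatorSpec(nClasses = 18, seed = 31))
  g2 <- generateOntology(generatorSpec(nClasses = 18, seed = 31))
  expect_identical(scoreFrame(evaluateOntology(g1)),
                   scoreFrame(evaluateOntology(g2)))
})

test_that("a metric vector in every top band saturates all scores at 5", {
  ## a model whose bands sit below any attainable value (higher-better)
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "metrics:",
    paste0("  ", metricNames(),
           ": {direction: higher, bands: [-4, -3, -2, -1]}"),
    "subcharacteristics:",
    "  OnlyOne: [LCOMOnto, ANOnto]",
    "characteristics:",
    "  Top: [OnlyOne]"), tmp)
  model <- readQualityModel(tmp)
  card <- evaluateOntology(chainGraph(), model)
  expect_true(all(metricScores(card) == 5L))
  expect_equal(unname(subcharacteristicScores(card)), 5)
  expect_equal(unname(characteristicScores(card)), 5)
})

test_that("degenerate metrics score 1 and are flagged on the card", {
  card <- evaluateOntology(makeGraph("A"))
  expect_identical(unname(metricScores(card)["NOCOnto"]), 1L)
  expect_true("NOCOnto" %in% card@degenerate)
})

test_that("quality model round-trips through YAML serialization", {
  model <- defaultQualityModel()
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeQualityModel(model, tmp)
  model2 <- readQualityModel(tmp)
  expect_equal(model@metrics, model2@metrics)
  expect_equal(model@subcharacteristics, model2@subcharacteristics)
  expect_equal(model@characteristics, model2@characteristics)
})

test_that("score bounds hold across a randomized battery of ontologies", {
  model <- defaultQualityModel()
  for (seed in 301:360) {
    g <- generateOntology(randomSpec(seed, maxClasses = 30L))
    sf <- scoreFrame(evaluateOntology(g, model))
    expect_true(all(sf$score >= 1 & sf$score <= 5),
                label = paste("seed", seed))
  }
})

test_that("invalid quality models are rejected at load time", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "metrics:",
    "  ANOnto: {direction: higher, bands: [3, 2, 1, 0]}",
    "subcharacteristics:",
    "  S: [ANOnto]",
    "characteristics:",
    "  C: [S]"), tmp)
  expect_error(readQualityModel(tmp), "increasing")
  writeLines(c(
    "metrics:",
    "  ANOnto: {direction: higher, bands: [1, 2, 3, 4]}",
    "subcharacteristics:",
    "  S: [NotAMetric]",
    "characteristics:",
    "  C: [S]"), tmp)
  expect_error(readQualityModel(tmp), "undefined metric")
})
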