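---
title: "Structural quality scoring of OWL ontologies and trial-style evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural quality scoring of OWL ontologies and trial-style evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oquare)
```

## The quality model

The package scores OWL 2 ontologies on the 1–5 SQuaRE-style quality
scale through three layers:

1. **Twelve structural metrics** computed on the *asserted* class
   hierarchy and axioms of a single document.  Everything is a ratio of
   assertion counts — subclass axioms, property domain declarations,
   property occurrences inside anonymous restrictions, individual
   membership assertions, class annotations — never of declared-entity
   counts.  Two axioms asserting the same thing count once.
2. **Threshold banding.**  Each metric has a direction (higher- or
   lower-is-better) and four strictly increasing cut points splitting
   its range into five bands; band index = integer score 1–5.  The
   boundary convention is half-open: a value exactly on a cut point
   belongs to the upper band.
3. **Weighted aggregation.**  A subcharacteristic score is the weighted
   mean of its metric scores; a characteristic score is the weighted
   mean of its subcharacteristic scores.  The shipped model has 29
   subcharacteristics and 7 characteristics, with equal weights at each
   level.  A metric may feed several subcharacteristics — annotation
   richness, for instance, feeds Knowledge Reuse, Redundancy and
   Controlled Vocabulary, since annotations make an ontology both more
   reusable and less ambiguous.

### Assumptions and conventions of the OWL reader

* **Asserted hierarchy only.**  No reasoner is invoked; parenthood is
  what the document asserts.  This is deliberate: the metrics are meant
  to characterize a modelling *artifact* as written, and good-practice
  guidance typically distinguishes asserted from inferred multiple
  parenthood.
* **No import resolution.**  Only the document's own axioms count;
  otherwise scores would depend on network state.
* **Anonymous class expressions are never classes.**  A restriction
  reached through `rdfs:subClassOf` or `owl:equivalentClass` counts
  once per occurrence in the restriction tally, and its `onProperty`
  counts once as a property assertion.  Equivalence axioms never
  create subclass edges.
* **`owl:Thing` handling.**  Asserted `A ⊑ owl:Thing` axioms are
  recorded but excluded from the edge totals used by the metrics, so a
  serializer's habit of asserting Thing-parenthood cannot inflate
  denominators.  Orphan classes are implicitly rooted at `owl:Thing`
  for path purposes, with the root attachment counting as one edge: a
  lone class has depth 1, not 0.
* **Restriction inventory is a switch.**  The inclusive convention
  (existential, universal, cardinality and value restrictions) is the
  default of `parseOWL(restrictionTypes = ...)`; a stricter inventory
  can be selected when a different counting convention must be
  matched.
* **RFCOnto** counts the property assertions *directly* attached to a
  class (domain declaration or restriction on that class).  Under this
  reading it coincides numerically with NOMOnto; the
  `rfcInherited = TRUE` switch extends "accessible" to ancestor-attached
  assertions, which is the other defensible reading of
  "directly accessed from the class".
* **NOCOnto** is defined in the literature by a name ("number of
  children") that conflicts with its prose ("direct superclasses per
  class minus the subclasses of Thing").  The package follows the
  prose: subclass-edge total divided by the number of classes that are
  not directly attached to the root.  The numerator is the same edge
  multiset under either orientation, so only the denominator convention
  matters, and it is the one stated.

### Numerical choices

* Any metric whose denominator is zero is reported as 0, scored 1, and
  flagged on the `MetricVector`/`ScoreCard` (`degenerateMetrics()`),
  keeping batch pipelines total while preserving auditability.
* Path statistics (mean and maximum root-to-leaf path length) are
  computed by dynamic programming in topological order, so the metric
  engine never materializes an exponential path set;
  `rootToLeafPaths()` provides the explicit enumeration, and the two
  are cross-checked in the test suite against a third, naive recursive
  implementation.
* Cycles in the subclass graph are detected and reported with a
  witness cycle rather than silently truncated.

### The shipped constants are a reconstruction

The aggregation *mechanism* is fixed by the framework; the *constants*
(band cut points, the metric↔subcharacteristic incidence, the weights)
are not part of any archival publication and live entirely in
`inst/extdata/oquare-model.yaml`.  The shipped matrix is a documented
reconstruction anchored on the relationships that are stated in the
literature (annotation richness → Knowledge Reuse / Redundancy /
Controlled Vocabulary; multiple-parenthood metrics → Tangledness; path
cohesion → Cohesion / Modularity), completed by object-oriented-metrics
practice for the remaining cells; six of the functional
subcharacteristics are driven by the single relational-richness metric
PROnto and therefore move together.  Scores are comparable *within* a
configuration, which is all the statistical pipeline needs; absolute
values depend on these constants and should not be compared across
configurations.  Every entry can be overridden via
`readQualityModel()`.

Default bands were chosen once for small hand-built task ontologies
(tens of classes): depth and cohesion bands step at 2/4/6/8 edges;
per-class rate metrics band near [0, 1]; property-count metrics step at
0.5/1/2/3 per class.  Directions follow software-metric practice:
complexity/coupling-like metrics (LCOMOnto, WMCOnto, DITOnto, NOCOnto,
RFCOnto, NOMOnto) are lower-is-better, richness-like metrics (ANOnto,
AROnto, CROnto, INROnto, PROnto, NACOnto) higher-is-better.

## The synthetic cohort generator

`generateCohort()` emulates the design of a crossed training trial: 24
students, six topics (PRO, IMM, CME, INF, CLO, SPA) with two tasks
each — 288 ontologies — plus two gold-standard ontologies per topic.
Students split into two groups; group A is trained on PRO, IMM and
CLO, group B on the remaining three, so each topic has a trained and
an untrained arm of equal size.  `sampleBalanced(co, 18)` reproduces
the balanced subsampling step: 18 retained files per task (9 per arm),
216 in total, with a repair pass guaranteeing every student remains
represented — the only constraint the design states, enforced
globally.

Each (student, topic, task) cell owns an RNG substream derived from
the master seed, so discarding files never perturbs the remaining
ontologies.

The trained arm draws from effect-shifted generator parameters.  The
default profile lowers the multiple-parenthood probability by 0.15 and
raises annotation coverage by 0.10 — the directions in which
guideline-based training is expected to move novice modellers (less
asserted multiple inheritance, more documentation).  The magnitudes
are free parameters chosen once to give a clearly detectable but not
saturating signal at 9-per-cell sample sizes; they are not estimates
of any real training effect.  The gold-standard spec is fully
annotated and single-parented.

What the generator does *not* emulate: linguistically meaningful class
names, real upper-ontology content, correlated error structure between
a student's twelve files (cells are independent), and non-structural
quality (semantic correctness, coverage).  Green tests therefore
certify the measurement and analysis machinery, not any claim about
real student ontologies.

## The statistical pipeline

* `anovaTrainingByTopic()` — fixed-effects two-way ANOVA with
  interaction (`score ~ arm * topic`).  Only balanced tables are
  accepted: with equal cell sizes the factorial decomposition is
  unique and the F-test is robust to mild non-normality, which is the
  design argument for subsampling to balance in the first place.
  Degenerate zero-variance inputs give p = 1 by convention.
* `ttestByTopic()` — Student's t-test per topic, pooled variance by
  default (equal arm sizes), Welch under a flag; per-arm 95% t-based
  confidence intervals.
* `distanceToGold()` — `d = |G − x̄|` per (subcharacteristic, topic,
  arm), where `G` is the mean score of the topic's gold ontologies.
  The result is the matrix pair `D1` (untrained) and `D2` (trained),
  29 × 6.  A `transform` hook accepts any alternative distance.
* `hierCluster()` — Euclidean distance over rows, Ward's
  minimum-variance linkage (`ward.D2`, i.e. on the distances proper),
  tree cut at k = 4 by default; centers are per-group column means.
* `kmeansCluster()` — k-means with 25 restarts under a fixed seed,
  reporting between-group variance explained as a percentage.  When k
  equals the number of distinct rows the exact optimum (each row its
  own center, 100% explained) is returned directly.
* `pcaOrder()` — column-centered covariance PCA (correlation PCA under
  `scale = TRUE`; covariance is the default because all columns are
  already on the common 1–5 score scale), ordering subcharacteristics
  by their first-component score.  A zero-variance matrix returns the
  defined degenerate output (all-zero scores, input order).

Multiple-testing correction is deliberately **off** by default — the
pipeline reports raw per-test significance, as outcome analyses of
this design conventionally do — and can be applied downstream
(`p.adjust`) if desired.

## Problem sizes used by the shipped tests

The test suite exercises: metric equivalence against a brute-force
oracle on 200 random DAG ontologies of up to 50 classes; score-bound
checks over a 500-ontology randomized battery; type-I calibration of
the interaction F-test and the t-test at 1000 null replicates
(nominal 0.05, accepted within ±0.02); power of the interaction test
at a single-topic 1.0-score shift, σ = 0.5, 9 per cell (noncentrality
≈ 15, theoretical power ≈ 0.84); planted-structure recovery for Ward,
k-means and PCA on 29 × 6 matrices; and 100-seed generate → write →
parse round-trips.  These sizes were chosen as the smallest that pin
down each property sharply.

## Known limitations

* The RDF/XML reader covers the constructs the metrics need (class
  declarations, subclass/equivalence axioms, restrictions, domains,
  typed individuals, annotations) in the serialization styles produced
  by mainstream editors and by `writeOWL()`; it is not a general RDF
  triple store, and exotic serializations (RDF lists of axioms,
  reification) are out of scope.
* Scores depend on the configurable constants; cross-configuration
  comparisons are meaningless.
* The statistics assume the balanced design they enforce; unbalanced
  observational data would need a different (Type-II/III) analysis,
  which is intentionally not provided.

## A compact session

```{r example}
g <- parseOWL(system.file("extdata", "chain3.owl", package = "oquare"))
metricValues(computeMetrics(g))

co  <- generateCohort(cohortDesign(students = 6), seed = 1)
tab <- buildScoreTable(co)
anovaTrainingByTopic(tab, "Tangledness")$training
```
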