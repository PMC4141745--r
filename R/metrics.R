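#' Names of the twelve structural metrics
#'
#' @return character vector in canonical order: LCOMOnto, WMCOnto,
#'   DITOnto, NACOnto, NOCOnto, RFCOnto, NOMOnto, PROnto, AROnto,
#'   INROnto, CROnto, ANOnto.
#' @export
metricNames <- function() {
  c("LCOMOnto", "WMCOnto", "DITOnto", "NACOnto", "NOCOnto", "RFCOnto",
    "NOMOnto", "PROnto", "AROnto", "INROnto", "CROnto", "ANOnto")
}

#' Compute the twelve structural quality metrics of an ontology
#'
#' All metrics are ratios of assertion counts (not declared-entity
#' counts) over the asserted class hierarchy; no reasoning is performed.
#' With `E` the named subclass-edge total, `P` the property assertions
#' (domain declarations plus restriction occurrences, object + datatype),
#' `R` the restriction count, `n` the number of classes:
#'
#' * `LCOMOnto` - mean length of the distinct root-to-leaf paths;
#' * `WMCOnto` - `(P + E) / n`;
#' * `DITOnto` - length of the longest root-to-leaf path (edges; a single
#'   orphan class has depth 1);
#' * `NACOnto` - mean number of direct superclasses per leaf class
#'   (orphan leaves count 1 for their implicit root attachment);
#' * `NOCOnto` - `E` divided by the number of classes not directly
#'   attached to the root;
#' * `RFCOnto` - property assertions directly attached to a class (via a
#'   domain declaration or a restriction on that class), averaged over
#'   classes; with `rfcInherited = TRUE` assertions attached to ancestor
#'   classes are also accessible and counted;
#' * `NOMOnto` - `P / n`;
#' * `PROnto` - `P / (E + P)`;
#' * `AROnto` - `R / n`;
#' * `INROnto` - `E / n`;
#' * `CROnto` - individual membership assertions per class;
#' * `ANOnto` - class annotation assertions per class.
#'
#' A metric whose denominator is zero is reported as 0 and flagged
#' degenerate (see [degenerateMetrics()]) so that scoring pipelines stay
#' total.
#'
#' @param g an [OntologyGraph]; cycles in the hierarchy raise an error.
#' @param rfcInherited if `TRUE`, RFCOnto counts property assertions on a
#'   class and all its ancestors.
#' @return a [MetricVector].
#' @examples
#' g <- generateOntology(generatorSpec(nClasses = 12, seed = 1))
#' metricValues(computeMetrics(g))
#' @export
computeMetrics <- function(g, rfcInherited = FALSE) {
  stopifnot(is(g, "OntologyGraph"))
  n <- length(g@classes)
  values <- setNames(numeric(12), metricNames())
  degenerate <- character()
  if (n == 0L) {
    return(new("MetricVector", values = values,
               degenerate = metricNames()))
  }

  idx <- hierarchyIndex(g)
  ps <- pathStats(g)
  E <- nrow(g@edges)
  P <- propertyAssertions(g)
  R <- nrow(g@restrictions)

  values[["LCOMOnto"]] <- ps$sumLen / ps$nPaths
  values[["DITOnto"]] <- ps$maxLen
  values[["WMCOnto"]] <- (P + E) / n
  values[["NOMOnto"]] <- P / n
  values[["AROnto"]] <- R / n
  values[["INROnto"]] <- E / n
  values[["CROnto"]] <- nrow(g@individuals) / n
  values[["ANOnto"]] <- nrow(g@annotations) / n

  leaves <- idx$classes[idx$leaves]
  nac <- vapply(leaves, function(cls) {
    p <- idx$nParents[[match(cls, idx$classes)]] +
      (cls %in% g@thingChildren)
    if (p == 0L) 1 else as.numeric(p)
  }, numeric(1))
  values[["NACOnto"]] <- mean(nac)

  nonRoot <- sum(idx$nParents > 0L)
  if (nonRoot > 0L) {
    values[["NOCOnto"]] <- E / nonRoot
  } else {
    degenerate <- c(degenerate, "NOCOnto")
  }

  if (rfcInherited) {
    direct <- propertyAssertions(g, perClass = TRUE)
    to <- topoOrder(g)
    acc <- setNames(numeric(n), idx$classes)
    for (v in to$order) {
      reach <- direct[[v]]
      ## accessible set = own assertions plus everything on ancestors;
      ## union over parents can double count shared ancestors, so walk
      ## the ancestor set explicitly (n <= a few hundred in practice)
      anc <- character(0); frontier <- idx$parents[[v]]
      while (length(frontier)) {
        anc <- union(anc, frontier)
        frontier <- setdiff(unique(unlist(idx$parents[frontier])), anc)
      }
      acc[[v]] <- reach + sum(direct[anc])
    }
    values[["RFCOnto"]] <- mean(acc)
  } else {
    values[["RFCOnto"]] <- P / n
  }

  if (E + P > 0) {
    values[["PROnto"]] <- P / (E + P)
  } else {
    degenerate <- c(degenerate, "PROnto")
  }

  new("MetricVector", values = values, degenerate = degenerate)
}
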