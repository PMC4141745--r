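#' @importFrom methods new validObject is slot "slot<-" slotNames
#' @importFrom stats aov rbinom rpois runif setNames qt sd var dist hclust
#'   cutree kmeans prcomp pt t.test
#' @importFrom utils write.csv read.csv packageVersion
NULL

## IRI of the hierarchy root used for implicit rooting of orphan classes.
OWL_THING <- "http://www.w3.org/2002/07/owl#Thing"

NS_RDF  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
NS_RDFS <- "http://www.w3.org/2000/01/rdf-schema#"
NS_OWL  <- "http://www.w3.org/2002/07/owl#"
NS_XSD  <- "http://www.w3.org/2001/XMLSchema#"

## Standard annotation properties always counted as class annotations.
STD_ANNOTATION_PROPS <- c(
  paste0(NS_RDFS, c("label", "comment", "seeAlso", "isDefinedBy")),
  paste0(NS_OWL, "versionInfo")
)

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' that generator calls are reproducible without disturbing the global
#' random stream.
#'
#' @param seed integer seed, or `NA` to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.na(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a substream seed from a master seed
#'
#' One RNG stream per unit of work (e.g. one per student x topic x task
#' cell), so that subsetting a cohort never perturbs unrelated draws.
#' Multiplicative hashing modulo a Mersenne prime keeps the result a valid
#' 32-bit seed.
#'
#' @param seed master integer seed.
#' @param index positive integer stream index.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
deriveSeed <- function(seed, index) {
  m <- 2147483647
  x <- (as.double(seed) %% m + 1)
  for (k in as.double(index)) {
    x <- (x * 48271 + k * 16807 + 1) %% m
  }
  as.integer(x)
}

## Escape a string for inclusion in XML text or attribute content.
xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

## Empty prototype tables used by OntologyGraph slots.
emptyEdges <- function() {
  data.frame(child = character(), parent = character(),
             stringsAsFactors = FALSE)
}

emptyDomains <- function() {
  data.frame(property = character(), class = character(),
             kind = character(), stringsAsFactors = FALSE)
}

emptyRestrictions <- function() {
  data.frame(class = character(), property = character(),
             kind = character(), type = character(), filler = character(),
             axiom = character(), stringsAsFactors = FALSE)
}

emptyIndividuals <- function() {
  data.frame(individual = character(), class = character(),
             stringsAsFactors = FALSE)
}

emptyAnnotations <- function() {
  data.frame(class = character(), property = character(),
             value = character(), stringsAsFactors = FALSE)
}
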