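## Hierarchy helpers shared by the path enumerator and the metric engine.
## A class is root-attached (an edge from owl:Thing exists for path
## purposes) iff it has no asserted named parent, or it carries an
## asserted subClassOf owl:Thing axiom.

hierarchyIndex <- function(g) {
  classes <- g@classes
  parents <- split(g@edges$parent, factor(g@edges$child, levels = classes))
  children <- split(g@edges$child, factor(g@edges$parent, levels = classes))
  nParents <- lengths(parents)
  rootAttached <- nParents == 0L | classes %in% g@thingChildren
  leaves <- lengths(children) == 0L
  list(classes = classes, parents = parents, children = children,
       nParents = nParents, rootAttached = setNames(rootAttached, classes),
       leaves = setNames(leaves, classes))
}

## Kahn topological order over the named subclass edges; errors with one
## cycle if the graph is not a DAG.
topoOrder <- function(g) {
  idx <- hierarchyIndex(g)
  indeg <- idx$nParents
  queue <- idx$classes[indeg == 0L]
  order <- character(0)
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    order <- c(order, v)
    for (ch in idx$children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < length(idx$classes)) {
    leftover <- setdiff(idx$classes, order)
    ## walk parent links inside the leftover set until a repeat: a cycle
    walk <- leftover[[1]]
    while (!anyDuplicated(walk)) {
      p <- intersect(idx$parents[[walk[[length(walk)]]]], leftover)[[1]]
      walk <- c(walk, p)
    }
    cyc <- walk[which(walk == walk[[length(walk)]])[1]:length(walk)]
    stop("cycle in subclass hierarchy: ",
         paste(rev(cyc), collapse = " -> "), call. = FALSE)
  }
  list(order = order, index = idx)
}

#' Enumerate all root-to-leaf paths of the class hierarchy
#'
#' Follows asserted subclass edges downwards from `owl:Thing`, starting at
#' every root-attached class (a class with no asserted named parent, or
#' with an asserted `owl:Thing` parent), and enumerates each distinct
#' directed path ending at a leaf class (a class with no asserted
#' subclasses).  Path length is the number of edges traversed, so a single
#' orphan class sits at depth 1.
#'
#' @param g an [OntologyGraph]; its subclass hierarchy must be acyclic
#'   (a cycle raises an error identifying it).
#' @return list of character vectors, each starting at the `owl:Thing` IRI
#'   and ending at a leaf class.
#' @seealso [computeMetrics()], which consumes path statistics.
#' @export
rootToLeafPaths <- function(g) {
  to <- topoOrder(g)   # also performs cycle detection
  idx <- to$index
  paths <- list()
  descend <- function(prefix, cls) {
    prefix <- c(prefix, cls)
    kids <- idx$children[[cls]]
    if (!length(kids)) {
      paths[[length(paths) + 1L]] <<- prefix
    } else {
      for (k in kids) descend(prefix, k)
    }
  }
  for (cls in idx$classes[idx$rootAttached]) descend(OWL_THING, cls)
  paths
}

## Path statistics by dynamic programming in topological order:
## number of root-to-v paths, their total length and the longest one.
## Used by the metric engine; rootToLeafPaths() is the enumerating
## counterpart.
pathStats <- function(g) {
  to <- topoOrder(g)
  idx <- to$index
  n <- length(idx$classes)
  if (n == 0L)
    return(list(nPaths = 0, sumLen = 0, maxLen = 0))
  npath <- setNames(numeric(n), idx$classes)
  slen <- setNames(numeric(n), idx$classes)
  mlen <- setNames(numeric(n), idx$classes)
  for (v in to$order) {
    root <- idx$rootAttached[[v]]
    npath[[v]] <- as.numeric(root)
    slen[[v]] <- as.numeric(root)   # one path of length 1 via Thing
    mlen[[v]] <- if (root) 1 else 0
    for (p in idx$parents[[v]]) {
      npath[[v]] <- npath[[v]] + npath[[p]]
      slen[[v]] <- slen[[v]] + slen[[p]] + npath[[p]]
      mlen[[v]] <- max(mlen[[v]], mlen[[p]] + 1)
    }
  }
  leafNames <- idx$classes[idx$leaves]
  list(nPaths = sum(npath[leafNames]), sumLen = sum(slen[leafNames]),
       maxLen = if (length(leafNames)) max(mlen[leafNames]) else 0)
}
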