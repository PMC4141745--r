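## Independent brute-force oracles.  These deliberately avoid the
## package's dynamic-programming path statistics: paths are enumerated by
## naive recursion over the edge table, and every metric is recomputed
## from first principles with plain loops.

oraclePaths <- function(g) {
  e <- g@edges
  parentsOf <- function(cl) e$parent[e$child == cl]
  kidsOf <- function(cl) e$child[e$parent == cl]
  roots <- g@classes[vapply(g@classes, function(cl)
    length(parentsOf(cl)) == 0L || cl %in% g@thingChildren, logical(1))]
  paths <- list()
  walk <- function(prefix, cl) {
    kids <- kidsOf(cl)
    if (!length(kids)) paths[[length(paths) + 1L]] <<- c(prefix, cl)
    else for (k in kids) walk(c(prefix, cl), k)
  }
  for (r in roots) walk(character(), r)
  paths   # length(vec) == edge count including the root attachment
}

oracleMetrics <- function(g) {
  n <- length(g@classes)
  paths <- oraclePaths(g)
  lens <- lengths(paths)
  e <- g@edges
  leaves <- g@classes[!(g@classes %in% e$parent)]
  nac <- vapply(leaves, function(cl) {
    p <- sum(e$child == cl) + (cl %in% g@thingChildren)
    if (p == 0) 1 else p
  }, numeric(1))
  P <- nrow(g@propertyDomains) + nrow(g@restrictions)
  E <- nrow(e)
  nonRoot <- sum(vapply(g@classes, function(cl) any(e$child == cl),
                        logical(1)))
  c(LCOMOnto = mean(lens),
    WMCOnto = (P + E) / n,
    DITOnto = max(lens),
    NACOnto = mean(nac),
    NOCOnto = if (nonRoot > 0) E / nonRoot else 0,
    RFCOnto = P / n,
    NOMOnto = P / n,
    PROnto = if (E + P > 0) P / (E + P) else 0,
    AROnto = nrow(g@restrictions) / n,
    INROnto = E / n,
    CROnto = nrow(g@individuals) / n,
    ANOnto = nrow(g@annotations) / n)
}

## random generator specs for property-style batteries
randomSpec <- function(seed, maxClasses = 50L) {
  withSeed(seed, generatorSpec(
    nClasses = sample(2:maxClasses, 1L),
    maxDepth = sample(2:6, 1L),
    branching = sample(c("uniform", "preferential"), 1L),
    multiParentProb = runif(1, 0, 0.4),
    objPropRate = runif(1, 0, 1),
    dataPropRate = runif(1, 0, 0.6),
    restrictionRate = runif(1, 0, 1),
    annotationCoverage = runif(1),
    individualsRate = runif(1, 0, 0.8),
    seed = seed))
}

## balanced two-way sums of squares from cell means, first principles
oracleTwoWaySS <- function(df) {
  gm <- mean(df$score)
  arms <- unique(df$arm); topics <- unique(df$topic)
  nCell <- nrow(df) / (length(arms) * length(topics))
  ssA <- 0
  for (a in arms) ssA <- ssA +
    length(topics) * nCell * (mean(df$score[df$arm == a]) - gm)^2
  ssB <- 0
  for (b in topics) ssB <- ssB +
    length(arms) * nCell * (mean(df$score[df$topic == b]) - gm)^2
  ssAB <- 0; ssE <- 0
  for (a in arms) for (b in topics) {
    cell <- df$score[df$arm == a & df$topic == b]
    ssAB <- ssAB + nCell * (mean(cell) - mean(df$score[df$arm == a]) -
                              mean(df$score[df$topic == b]) + gm)^2
    ssE <- ssE + sum((cell - mean(cell))^2)
  }
  c(training = ssA, topic = ssB, interaction = ssAB, residual = ssE,
    total = sum((df$score - gm)^2))
}

## simulated balanced score tables for calibration studies
simulateScoreTable <- function(nPerCell = 9, topics = c("PRO", "IMM",
                                 "CME", "INF", "CLO", "SPA"),
                               shift = 0, shiftTopic = NULL, sigma = 0.5,
                               mu = 3) {
  rows <- expand.grid(rep = seq_len(nPerCell),
                      arm = c("untrained", "trained"), topic = topics,
                      stringsAsFactors = FALSE)
  rows$score <- mu + stats::rnorm(nrow(rows), 0, sigma)
  if (!is.null(shiftTopic)) {
    hit <- rows$arm == "trained" & rows$topic == shiftTopic
    rows$score[hit] <- rows$score[hit] + shift
  } else if (shift != 0) {
    rows$score[rows$arm == "trained"] <-
      rows$score[rows$arm == "trained"] + shift
  }
  rows$subcharacteristic <- "SIM"
  rows
}

withSeed <- oquare:::withSeed
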