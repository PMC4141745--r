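#' Score every ontology of a cohort into a long score table
#'
#' Applies [evaluateOntology()] to each (labeled or gold) ontology and
#' returns one row per ontology and subcharacteristic (or metric /
#' characteristic when `level` says so).
#'
#' @param cohort an [OntologyCohort].
#' @param model a [QualityModel].
#' @param level which score level to tabulate.
#' @param gold if `TRUE`, score the gold-standard ontologies instead of
#'   the student ontologies (the `arm` column is then `"gold"`).
#' @return data.frame with columns `id`, `student`, `topic`, `task`,
#'   `arm`, `subcharacteristic` (or `metric`/`characteristic`) and
#'   `score`.  Evaluation failures are rethrown naming the offending
#'   ontology.
#' @export
buildScoreTable <- function(cohort, model = defaultQualityModel(),
                            level = c("subcharacteristic", "metric",
                                      "characteristic"),
                            gold = FALSE) {
  stopifnot(is(cohort, "OntologyCohort"))
  level <- match.arg(level)
  if (gold) {
    manifest <- cohort@goldManifest
    manifest$student <- NA_integer_
    manifest$arm <- "gold"
    graphs <- cohort@goldGraphs
  } else {
    manifest <- cohort@manifest
    graphs <- cohort@graphs
  }
  if (!nrow(manifest)) {
    out <- data.frame(id = character(), student = integer(),
                      topic = character(), task = integer(),
                      arm = character(), name = character(),
                      score = numeric(), stringsAsFactors = FALSE)
    names(out)[names(out) == "name"] <- level
    return(out)
  }
  pick <- switch(level, metric = metricScores,
                 subcharacteristic = subcharacteristicScores,
                 characteristic = characteristicScores)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$id[i]
    card <- tryCatch(
      evaluateOntology(graphs[[id]], model),
      error = function(e) stop("evaluation failed for '", id, "': ",
                               conditionMessage(e), call. = FALSE))
    sc <- pick(card)
    data.frame(id = id, student = manifest$student[i],
               topic = manifest$topic[i], task = manifest$task[i],
               arm = manifest$arm[i], name = names(sc),
               score = as.numeric(sc), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "name"] <- level
  rownames(out) <- NULL
  out
}

checkScoreTable <- function(tab, subcharacteristic) {
  need <- c("topic", "arm", "subcharacteristic", "score")
  if (!all(need %in% names(tab)))
    stop("score table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  sub <- tab[tab$subcharacteristic == subcharacteristic, , drop = FALSE]
  if (!nrow(sub))
    stop("no rows for subcharacteristic '", subcharacteristic, "'",
         call. = FALSE)
  sub
}

#' Two-way ANOVA of training by topic
#'
#' Fixed-effects two-way ANOVA with interaction for one
#' subcharacteristic: `score ~ arm * topic`.  The design must be
#' balanced (equal cell counts, at least two observations per cell);
#' unbalanced tables are rejected, because with unequal cell sizes the
#' factorial sums of squares are no longer uniquely defined.  When a
#' term's sum of squares is zero its p-value is reported as 1 (no
#' evidence); when the residual sum of squares is zero but a term's is
#' positive, the p-value is 0.
#'
#' @param tab long score table (see [buildScoreTable()]).
#' @param subcharacteristic subcharacteristic name to analyse.
#' @return list with elements `table` (data.frame: `term`, `df`,
#'   `sumsq`, `F`, `p`), and `training`, `topic`, `interaction` (each a
#'   list with `F` and `p`).
#' @export
anovaTrainingByTopic <- function(tab, subcharacteristic) {
  sub <- checkScoreTable(tab, subcharacteristic)
  cells <- table(sub$arm, sub$topic)
  if (length(unique(as.vector(cells))) != 1L)
    stop("unbalanced design: unequal cell sizes for '",
         subcharacteristic, "'", call. = FALSE)
  if (min(cells) < 2L)
    stop("need at least two observations per cell", call. = FALSE)
  sub$arm <- factor(sub$arm)
  sub$topic <- factor(sub$topic)
  fit <- aov(score ~ arm * topic, data = sub)
  an <- summary(fit)[[1]]
  tabOut <- data.frame(
    term = c("training", "topic", "interaction", "residual"),
    df = an[["Df"]], sumsq = an[["Sum Sq"]],
    F = an[["F value"]], p = an[["Pr(>F)"]],
    stringsAsFactors = FALSE
  )
  ssRes <- tabOut$sumsq[4]
  for (i in 1:3) {
    if (tabOut$sumsq[i] <= 1e-12 * max(sum(tabOut$sumsq), 1)) {
      tabOut$F[i] <- 0; tabOut$p[i] <- 1
    } else if (ssRes <= 1e-12 * sum(tabOut$sumsq)) {
      tabOut$F[i] <- Inf; tabOut$p[i] <- 0
    }
  }
  asTerm <- function(i) list(F = tabOut$F[i], p = tabOut$p[i])
  list(table = tabOut, training = asTerm(1), topic = asTerm(2),
       interaction = asTerm(3))
}

#' Two-sample t-test between arms within one topic
#'
#' Student's t-test (pooled variance by default, matching a balanced
#' design; `welch = TRUE` switches to the Welch approximation) comparing
#' untrained and trained scores of one subcharacteristic in one topic,
#' plus a 95% confidence interval for each arm's mean.  Degenerate
#' inputs with zero variance in both arms give `t = 0, p = 1` when the
#' means coincide and `p = 0` otherwise.
#'
#' @param tab long score table.
#' @param subcharacteristic subcharacteristic name.
#' @param topic topic code; both arms must be present.
#' @param welch use the Welch unequal-variance statistic.
#' @param conf confidence level for the per-arm mean intervals.
#' @return list with `t`, `p`, `df`, `means` (named numeric) and `ci`
#'   (2 x 2 matrix, rows untrained/trained).
#' @export
ttestByTopic <- function(tab, subcharacteristic, topic, welch = FALSE,
                         conf = 0.95) {
  sub <- checkScoreTable(tab, subcharacteristic)
  sub <- sub[sub$topic == topic, , drop = FALSE]
  x <- sub$score[sub$arm == "untrained"]
  y <- sub$score[sub$arm == "trained"]
  if (!length(x) || !length(y))
    stop("both arms must be present for topic '", topic, "'",
         call. = FALSE)
  armCI <- function(v) {
    m <- mean(v)
    if (length(v) < 2L || sd(v) == 0) return(c(m, m))
    half <- qt(1 - (1 - conf) / 2, length(v) - 1L) * sd(v) / sqrt(length(v))
    c(m - half, m + half)
  }
  ci <- rbind(untrained = armCI(x), trained = armCI(y))
  colnames(ci) <- c("lower", "upper")
  if (sd(x) == 0 && sd(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t = if (eq) 0 else Inf * sign(mean(x) - mean(y)),
                p = if (eq) 1 else 0,
                df = length(x) + length(y) - 2L,
                means = c(untrained = mean(x), trained = mean(y)),
                ci = ci))
  }
  ht <- t.test(x, y, var.equal = !welch, conf.level = conf)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter),
       means = c(untrained = mean(x), trained = mean(y)), ci = ci)
}

#' Distance-to-gold matrices for both arms
#'
#' For every (subcharacteristic, topic), computes
#' `d = |G - mean(scores)|` per arm, where `G` is the gold-standard
#' score for that cell (the mean over the topic's gold ontologies).
#' The result is the pair of matrices `D1` (untrained) and `D2`
#' (trained), one row per subcharacteristic, one column per topic.
#'
#' @param tab long score table of the student ontologies.
#' @param goldTab long score table of the gold standards (see
#'   `buildScoreTable(..., gold = TRUE)`).
#' @param transform optional function `f(G, xbar)` replacing the default
#'   absolute-difference distance.
#' @return list with elements `D1` and `D2`, each a labeled
#'   subcharacteristics x topics matrix with nonnegative entries.
#' @export
distanceToGold <- function(tab, goldTab, transform = NULL) {
  if (is.null(transform)) transform <- function(G, xbar) abs(G - xbar)
  subs <- unique(tab$subcharacteristic)
  topics <- unique(tab$topic)
  goldMean <- function(s, tp) {
    v <- goldTab$score[goldTab$subcharacteristic == s &
                         goldTab$topic == tp]
    if (!length(v))
      stop("missing gold score for (", s, ", ", tp, ")", call. = FALSE)
    mean(v)
  }
  armMatrix <- function(armName) {
    M <- matrix(NA_real_, length(subs), length(topics),
                dimnames = list(subs, topics))
    for (s in subs) for (tp in topics) {
      v <- tab$score[tab$subcharacteristic == s & tab$topic == tp &
                       tab$arm == armName]
      if (!length(v))
        stop("missing ", armName, " scores for (", s, ", ", tp, ")",
             call. = FALSE)
      M[s, tp] <- transform(goldMean(s, tp), mean(v))
    }
    M
  }
  list(D1 = armMatrix("untrained"), D2 = armMatrix("trained"))
}

#' Ward hierarchical clustering of subcharacteristic distance profiles
#'
#' Agglomerative clustering of the rows of a distance-to-gold matrix
#' using Euclidean distance and Ward's minimum-variance linkage, cut
#' into `k` groups.  Group labels are renumbered in order of first
#' appearance along the rows; centers are the per-group column means.
#'
#' @param D numeric matrix (subcharacteristics x topics).
#' @param k number of groups, `1 <= k <= nrow(D)`.
#' @return list with `assignment` (named integer vector), `centers`
#'   (k x ncol matrix) and `tree` (the [stats::hclust] object).
#' @export
hierCluster <- function(D, k = 4L) {
  if (k < 1L || k > nrow(D))
    stop("k must lie between 1 and the number of rows", call. = FALSE)
  tree <- hclust(dist(D, method = "euclidean"), method = "ward.D2")
  assignment <- cutree(tree, k = k)
  ## stable renumbering by first appearance
  relabel <- match(assignment, unique(assignment))
  assignment <- setNames(relabel, rownames(D))
  centers <- do.call(rbind, lapply(seq_len(k), function(gr)
    colMeans(D[assignment == gr, , drop = FALSE])))
  rownames(centers) <- seq_len(k)
  list(assignment = assignment, centers = centers, tree = tree)
}

#' k-means clustering of subcharacteristic distance profiles
#'
#' Standard k-means with multiple random restarts on the rows of a
#' distance-to-gold matrix, reporting the percentage of total variance
#' explained between groups and the within-group share per group.
#'
#' @param D numeric matrix (rows are clustered).
#' @param k number of groups.
#' @param seed integer seed (restarts are reproducible under it).
#' @param nstart random restarts.
#' @return list with `assignment`, `centers`, `explainedPct`
#'   (between-group sum of squares as % of total) and `withinPct`
#'   (per-group within sum of squares as % of total).
#' @export
kmeansCluster <- function(D, k = 4L, seed = 1L, nstart = 25L) {
  distinct <- unique(as.data.frame(D))
  if (k < 1L || k > nrow(distinct))
    stop("k must not exceed the number of distinct rows", call. = FALSE)
  if (k == nrow(distinct)) {
    ## exact optimum: every distinct row is its own center
    key <- apply(D, 1, paste, collapse = "\r")
    ukey <- apply(as.matrix(distinct), 1, paste, collapse = "\r")
    assignment <- setNames(match(key, ukey), rownames(D))
    centers <- as.matrix(distinct)
    rownames(centers) <- seq_len(k)
    return(list(assignment = assignment, centers = centers,
                explainedPct = 100, withinPct = rep(0, k)))
  }
  km <- withSeed(seed, kmeans(D, centers = k, nstart = nstart))
  relabel <- match(km$cluster, unique(km$cluster))
  assignment <- setNames(relabel, rownames(D))
  centers <- km$centers[unique(km$cluster), , drop = FALSE]
  rownames(centers) <- seq_len(k)
  totss <- km$totss
  explained <- if (totss > 0) 100 * km$betweenss / totss else 100
  within <- if (totss > 0) 100 * km$withinss[unique(km$cluster)] / totss
            else rep(0, k)
  list(assignment = assignment, centers = centers,
       explainedPct = explained, withinPct = unname(within))
}

#' Principal-component ordering of subcharacteristics
#'
#' Column-centered PCA (covariance PCA; `scale = TRUE` switches to
#' correlation PCA) of a distance-to-gold matrix.  Subcharacteristics
#' are ordered by their first-component score; topic loadings and the
#' percentage of variance per component are returned.  A matrix with no
#' variance yields zero scores and the input order.
#'
#' @param D numeric matrix (subcharacteristics x topics).
#' @param scale use correlation instead of covariance PCA.
#' @return list with `scores` (rows x components), `loadings`
#'   (topics x components), `varPct` (percent variance per component,
#'   summing to 100) and `order` (row names sorted by the first
#'   component score, ascending).
#' @export
pcaOrder <- function(D, scale = FALSE) {
  colVars <- apply(D, 2, var)
  if (all(colVars < .Machine$double.eps)) {
    ncomp <- min(dim(D))
    return(list(
      scores = matrix(0, nrow(D), ncomp,
                      dimnames = list(rownames(D),
                                      paste0("PC", seq_len(ncomp)))),
      loadings = matrix(0, ncol(D), ncomp,
                        dimnames = list(colnames(D),
                                        paste0("PC", seq_len(ncomp)))),
      varPct = rep(0, ncomp), order = rownames(D)))
  }
  pc <- prcomp(D, center = TRUE, scale. = scale)
  varPct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  ord <- rownames(D)[order(pc$x[, 1])]
  list(scores = pc$x, loadings = pc$rotation, varPct = varPct,
       order = ord)
}
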