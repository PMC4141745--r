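#' Construct a CohortDesign
#'
#' Defaults emulate a crossed two-arm training trial: 24 students, six
#' topics assessed by two tasks each (288 ontologies), group A trained on
#' PRO, IMM and CLO, group B on CME, INF and SPA.  The trained arm draws
#' its ontologies from effect-shifted generator parameters; by default
#' the training lowers asserted multiple parenthood and raises annotation
#' coverage.  Gold-standard ontologies use a fully annotated,
#' single-parent spec.
#'
#' @param students even number of students.
#' @param topics six topic codes.
#' @param tasksPerTopic tasks per topic.
#' @param groupATopics topics on which group A is trained (group B is
#'   trained on the rest).
#' @param baseSpec [GeneratorSpec] for the untrained arm.
#' @param goldSpec [GeneratorSpec] for gold-standard ontologies.
#' @param effect named list of numeric shifts applied to `baseSpec`
#'   parameters for the trained arm; either flat
#'   (`list(multiParentProb = -0.15)`, applied on every trained topic) or
#'   nested per topic (`list(PRO = list(...), ...)`).  Probabilities are
#'   clamped to `[0, 1]` and rates to nonnegative values after shifting.
#' @return a validated [CohortDesign].
#' @export
cohortDesign <- function(students = 24L,
                         topics = c("PRO", "IMM", "CME", "INF", "CLO",
                                    "SPA"),
                         tasksPerTopic = 2L,
                         groupATopics = c("PRO", "IMM", "CLO"),
                         baseSpec = generatorSpec(),
                         goldSpec = generatorSpec(multiParentProb = 0,
                                                  annotationCoverage = 1),
                         effect = list(multiParentProb = -0.15,
                                       annotationCoverage = 0.10)) {
  design <- new("CohortDesign", students = as.integer(students),
                topics = topics, tasksPerTopic = as.integer(tasksPerTopic),
                groupATopics = groupATopics, baseSpec = baseSpec,
                goldSpec = goldSpec, effect = effect)
  validObject(design)
  design
}

## Apply a trained-arm effect profile to a GeneratorSpec.
shiftSpec <- function(spec, shifts) {
  for (nm in names(shifts)) {
    if (!nm %in% slotNames(spec))
      stop("effect profile names unknown parameter '", nm, "'",
           call. = FALSE)
    val <- slot(spec, nm) + shifts[[nm]]
    if (nm %in% c("multiParentProb", "annotationCoverage"))
      val <- min(max(val, 0), 1)
    else val <- max(val, 0)
    slot(spec, nm) <- val
  }
  spec
}

effectForTopic <- function(effect, topic) {
  if (!length(effect)) return(list())
  if (all(vapply(effect, is.list, logical(1)))) {
    if (is.null(effect[[topic]])) list() else effect[[topic]]
  } else {
    effect
  }
}

#' Generate a labeled trial cohort of synthetic ontologies
#'
#' Produces `students x topics x tasksPerTopic` ontologies plus
#' `topics x tasksPerTopic` gold standards.  Students in the first half
#' form group A; an ontology is in the trained arm when its student's
#' group was trained on its topic.  Each (student, topic, task) cell uses
#' its own RNG substream derived from the master seed, so subsetting a
#' cohort never perturbs unrelated draws.
#'
#' @param design a [CohortDesign].
#' @param seed master integer seed.
#' @return an [OntologyCohort].
#' @examples
#' co <- generateCohort(cohortDesign(students = 4), seed = 1)
#' nrow(cohortManifest(co))  # 4 students x 6 topics x 2 tasks = 48
#' @export
generateCohort <- function(design, seed = 1L) {
  stopifnot(is(design, "CohortDesign"))
  validObject(design)
  nA <- design@students %/% 2L
  grid <- expand.grid(task = seq_len(design@tasksPerTopic),
                      topic = design@topics,
                      student = seq_len(design@students),
                      stringsAsFactors = FALSE)
  grid$group <- ifelse(grid$student <= nA, "A", "B")
  trainedTopics <- list(A = design@groupATopics,
                        B = setdiff(design@topics, design@groupATopics))
  grid$arm <- ifelse(mapply(function(g, t) t %in% trainedTopics[[g]],
                            grid$group, grid$topic),
                     "trained", "untrained")
  grid$id <- sprintf("s%02d_%s_t%d", grid$student, grid$topic, grid$task)

  graphs <- vector("list", nrow(grid))
  names(graphs) <- grid$id
  for (i in seq_len(nrow(grid))) {
    spec <- design@baseSpec
    if (grid$arm[i] == "trained")
      spec <- shiftSpec(spec, effectForTopic(design@effect, grid$topic[i]))
    graphs[[i]] <- generateOntology(spec, seed = deriveSeed(seed, i))
  }

  goldGrid <- expand.grid(task = seq_len(design@tasksPerTopic),
                          topic = design@topics, stringsAsFactors = FALSE)
  goldGrid$id <- sprintf("gold_%s_t%d", goldGrid$topic, goldGrid$task)
  goldGraphs <- vector("list", nrow(goldGrid))
  names(goldGraphs) <- goldGrid$id
  for (i in seq_len(nrow(goldGrid)))
    goldGraphs[[i]] <- generateOntology(
      design@goldSpec, seed = deriveSeed(seed, nrow(grid) + i))

  manifest <- grid[, c("id", "student", "topic", "task", "arm", "group")]
  rownames(manifest) <- NULL
  new("OntologyCohort", manifest = manifest, graphs = graphs,
      goldManifest = goldGrid[, c("id", "topic", "task")],
      goldGraphs = goldGraphs, seed = as.integer(seed))
}

#' Balanced random subsampling of a cohort
#'
#' For every (topic, task) cell, retains exactly `keepPerTask` ontologies
#' with equal numbers from the trained and untrained arms, discarding the
#' rest at random; a repair pass then guarantees that every student keeps
#' at least one ontology overall (swapping a retained ontology for a
#' discarded one of the same arm and cell when necessary).  With the
#' default design and `keepPerTask = 18`, 288 ontologies reduce to 216
#' with 9 trained and 9 untrained students per task.
#'
#' @param cohort an [OntologyCohort] with a complete design.
#' @param keepPerTask ontologies retained per (topic, task); must be even
#'   (half per arm) unless equal to the number of students (identity).
#' @param seed integer seed for the random discard.
#' @return a new, smaller [OntologyCohort] (gold standards unchanged).
#' @export
sampleBalanced <- function(cohort, keepPerTask = 18L, seed = 1L) {
  stopifnot(is(cohort, "OntologyCohort"))
  m <- cohort@manifest
  students <- sort(unique(m$student))
  keepPerTask <- as.integer(keepPerTask)
  if (keepPerTask > length(students))
    stop("keepPerTask exceeds the number of students", call. = FALSE)
  if (keepPerTask == length(students)) return(cohort)
  if (keepPerTask %% 2L != 0L)
    stop("keepPerTask must be even to balance the two arms",
         call. = FALSE)
  half <- keepPerTask %/% 2L

  withSeed(seed, {
    keep <- logical(nrow(m))
    cells <- split(seq_len(nrow(m)), list(m$topic, m$task), drop = TRUE)
    for (rows in cells) {
      for (armName in c("untrained", "trained")) {
        armRows <- rows[m$arm[rows] == armName]
        if (length(armRows) < half)
          stop("cell has fewer than keepPerTask/2 ontologies in the ",
               armName, " arm", call. = FALSE)
        keep[armRows[sample.int(length(armRows), half)]] <- TRUE
      }
    }
    ## repair pass: every student must retain at least one ontology
    repeat {
      lost <- setdiff(students, unique(m$student[keep]))
      if (!length(lost)) break
      s <- lost[[1]]
      fixed <- FALSE
      candidates <- which(!keep & m$student == s)
      if (length(candidates) > 1L) candidates <- sample(candidates)
      for (i in candidates) {
        cellRows <- which(keep & m$topic == m$topic[i] &
                            m$task == m$task[i] & m$arm == m$arm[i])
        counts <- table(m$student[keep])
        swappable <- cellRows[counts[as.character(m$student[cellRows])] >= 2]
        if (length(swappable)) {
          out <- swappable[sample.int(length(swappable), 1L)]
          keep[out] <- FALSE
          keep[i] <- TRUE
          fixed <- TRUE
          break
        }
      }
      if (!fixed)
        stop("cannot satisfy the all-students constraint", call. = FALSE)
    }
    newManifest <- m[keep, , drop = FALSE]
    rownames(newManifest) <- NULL
    new("OntologyCohort", manifest = newManifest,
        graphs = cohort@graphs[newManifest$id],
        goldManifest = cohort@goldManifest,
        goldGraphs = cohort@goldGraphs, seed = cohort@seed)
  })
}
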