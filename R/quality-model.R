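weightVector <- function(entry, what) {
  if (is.list(entry) && !is.null(names(entry)) && all(nzchar(names(entry)))) {
    w <- unlist(entry)
  } else if (is.character(entry) || is.list(entry)) {
    nms <- unlist(entry)
    w <- setNames(rep(1, length(nms)), nms)
  } else {
    stop("cannot interpret ", what, " entry", call. = FALSE)
  }
  if (sum(w) <= 0)
    stop("all-zero weights in ", what, call. = FALSE)
  w / sum(w)
}

#' Read a quality-model configuration
#'
#' Loads the threshold bands, metric-to-subcharacteristic and
#' subcharacteristic-to-characteristic mappings from a YAML (or JSON)
#' file.  Weighted lists may be written either as bare name lists (equal
#' weights) or as `name: weight` mappings; weights are normalized to sum
#' to one at load time.
#'
#' @param path file path to a YAML or JSON quality-model document.
#' @return a validated [QualityModel].
#' @seealso [defaultQualityModel()], [writeQualityModel()]
#' @export
readQualityModel <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  for (part in c("metrics", "subcharacteristics", "characteristics"))
    if (is.null(cfg[[part]]))
      stop("quality model is missing the '", part, "' section",
           call. = FALSE)
  m <- do.call(rbind, lapply(names(cfg$metrics), function(nm) {
    e <- cfg$metrics[[nm]]
    bands <- as.numeric(unlist(e$bands))
    if (length(bands) != 4)
      stop("metric '", nm, "' needs exactly 4 band cut points",
           call. = FALSE)
    data.frame(metric = nm, direction = e$direction, b1 = bands[1],
               b2 = bands[2], b3 = bands[3], b4 = bands[4],
               stringsAsFactors = FALSE)
  }))
  subs <- lapply(cfg$subcharacteristics, weightVector,
                 what = "subcharacteristic")
  chars <- lapply(cfg$characteristics, weightVector,
                  what = "characteristic")
  model <- new("QualityModel", metrics = m, subcharacteristics = subs,
               characteristics = chars)
  validObject(model)
  model
}

#' The default quality model shipped with the package
#'
#' Twelve metrics, 29 subcharacteristics and 7 characteristics with equal
#' weights inside each aggregation level; see
#' `system.file("extdata", "oquare-model.yaml", package = "oquare")` for
#' the documented constants.
#'
#' @return a [QualityModel].
#' @export
defaultQualityModel <- function() {
  readQualityModel(system.file("extdata", "oquare-model.yaml",
                               package = "oquare", mustWork = TRUE))
}

#' Serialize a quality model back to YAML
#'
#' Writes the normalized model; reading the result back yields an
#' identical model.
#'
#' @param model a [QualityModel].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeQualityModel <- function(model, path) {
  stopifnot(is(model, "QualityModel"))
  metrics <- lapply(seq_len(nrow(model@metrics)), function(i) {
    row <- model@metrics[i, ]
    list(direction = row$direction,
         bands = c(row$b1, row$b2, row$b3, row$b4))
  })
  names(metrics) <- model@metrics$metric
  out <- list(
    metrics = metrics,
    subcharacteristics = lapply(model@subcharacteristics, as.list),
    characteristics = lapply(model@characteristics, as.list)
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
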