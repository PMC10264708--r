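#' Compute the trait series of a frame sequence
#'
#' Runs [binarize()] and [extractTraits()] on every frame of a manifest,
#' in timestamp order. A failure on an individual frame (unreadable file,
#' degenerate image) is recorded as an absent-trait row and never aborts
#' the series. Emergence is detected afterwards with
#' [detectEmergence()].
#'
#' @param manifest a non-empty [SeriesManifest].
#' @param landmarks [Landmarks] for the series.
#' @param config configuration from [rtConfig()]; `config$rule` is the
#'   threshold rule, `config$scale_mm_per_px` the physical scale.
#' @return A [TraitSeries].
#' @export
computeSeries <- function(manifest, landmarks, config = rtConfig()) {
  ent <- manifest@entries
  if (!nrow(ent)) stop("empty manifest")
  rows <- vector("list", nrow(ent))
  for (i in seq_len(nrow(ent))) {
    rows[[i]] <- tryCatch({
      mask <- binarize(readFrame(ent$path[i]), config$rule,
                       scale = config$scale_mm_per_px)
      extractTraits(mask, landmarks, config,
                    frameId = ent$frame_id[i],
                    timestampHAS = ent$timestamp_has[i])
    }, error = function(e) {
      r <- .zeroRecord(ent$frame_id[i], ent$timestamp_has[i])
      r[, !(names(r) %in% c("frame_id", "timestamp_has"))] <- NA
      r
    })
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  series <- new("TraitSeries", records = records, emergenceHAS = NA_real_,
                landmarks = landmarks, config = config)
  series@emergenceHAS <- detectEmergence(series, config$min_area_px)
  series
}

#' Detect root emergence in a trait series
#'
#' Emergence is the timestamp of the first record whose root area reaches
#' `minAreaPx` pixels (i.e. `minAreaPx * scale^2` in mm^2) and stays
#' there for two consecutive frames, which rejects single-frame speckle.
#' Absent (`NA`) if the threshold is never sustained.
#'
#' @param series a [TraitSeries] (computed with seed exclusion applied,
#'   so the grain body does not trigger detection).
#' @param minAreaPx area threshold in pixels (>= 1).
#' @return Hours after sowing, or `NA`.
#' @export
detectEmergence <- function(series, minAreaPx = 20) {
  rec <- series@records
  if (nrow(rec) < 2) return(NA_real_)
  scale <- series@config$scale_mm_per_px
  if (is.null(scale)) scale <- 1
  thr <- minAreaPx * scale^2
  ok <- !is.na(rec$root_area) & rec$root_area >= thr
  sustained <- ok[-length(ok)] & ok[-1]
  i <- which(sustained)
  if (!length(i)) return(NA_real_)
  rec$timestamp_has[i[1]]
}

#' Export a trait series as CSV
#'
#' One row per record with the fixed header [traitColumns()]; absent
#' values are written as empty cells.
#'
#' @param series a [TraitSeries].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
exportSeriesCsv <- function(series, path) {
  utils::write.csv(series@records[, traitColumns(), drop = FALSE], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Import a trait series from CSV
#'
#' Re-reads a file written by [exportSeriesCsv()]; empty cells become
#' `NA`. The landmarks and configuration are not stored in the CSV and
#' can be re-supplied.
#'
#' @param path CSV path.
#' @param landmarks [Landmarks] to attach (a placeholder by default).
#' @param config configuration list to attach.
#' @return A [TraitSeries]; emergence is re-detected from the records.
#' @export
importSeriesCsv <- function(path, landmarks = NULL, config = rtConfig()) {
  if (is.null(landmarks))
    landmarks <- landmarks(c(0, 0), seedExclusionRadius = 0)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(traitColumns(), names(rec))
  if (length(miss))
    stop("not a trait series CSV; missing columns: ",
         paste(miss, collapse = ", "))
  rec <- rec[, traitColumns(), drop = FALSE]
  ints <- c("frame_id", "n_endpoints", "n_junctions")
  for (cl in setdiff(traitColumns(), ints))
    rec[[cl]] <- as.numeric(rec[[cl]])  # all-NA columns read as logical
  for (cl in ints[-1]) rec[[cl]] <- as.integer(rec[[cl]])
  series <- new("TraitSeries", records = rec, emergenceHAS = NA_real_,
                landmarks = landmarks, config = config)
  series@emergenceHAS <- detectEmergence(series, config$min_area_px)
  series
}

#' Export a trait series as JSON with provenance
#'
#' Writes records, detected emergence, configuration snapshot and package
#' version into one JSON document.
#'
#' @param series a [TraitSeries].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
exportSeriesJson <- function(series, path) {
  cfg <- series@config
  cfg$rule <- unclass(cfg$rule)
  jsonlite::write_json(list(
    tool = "rhizotrack",
    version = as.character(utils::packageVersion("rhizotrack")),
    config = cfg,
    grain = series@landmarks@grain,
    seed_exclusion_radius = series@landmarks@seedExclusionRadius,
    emergence_has = series@emergenceHAS,
    records = series@records
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
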