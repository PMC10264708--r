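#' @useDynLib rhizotrack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Binary root mask
#'
#' A boolean pixel grid marking root foreground, together with the physical
#' scale of the image. The pixel coordinate convention used throughout the
#' package is 0-based, x rightward, y downward, origin at the top-left
#' pixel; the grid is stored as a matrix indexed `grid[y + 1, x + 1]`.
#'
#' @slot grid logical matrix, `TRUE` = root foreground.
#' @slot scale physical scale in mm per pixel (single positive number;
#'   1.0 means traits are reported in pixel units).
#'
#' @seealso [binarize()], [cleanMask()], [skeletonize()]
#' @export
setClass("BinaryRootMask",
  representation(grid = "matrix", scale = "numeric"),
  prototype(grid = matrix(logical(0), 0, 0), scale = 1))

setValidity("BinaryRootMask", function(object) {
  msg <- character()
  if (!is.logical(object@grid))
    msg <- c(msg, "grid must be a logical matrix")
  if (anyNA(object@grid))
    msg <- c(msg, "grid must not contain NA")
  if (length(object@scale) != 1 || is.na(object@scale) || object@scale <= 0)
    msg <- c(msg, "scale must be a single positive number (mm per pixel)")
  if (length(msg)) msg else TRUE
})

#' One-pixel root skeleton
#'
#' A topology-preserving one-pixel-wide reduction of a [BinaryRootMask].
#' Inherits the grid/scale representation of its source mask; every skeleton
#' pixel is a foreground pixel of that mask and the number of 8-connected
#' components is preserved.
#'
#' @seealso [skeletonize()], [buildGraph()]
#' @export
setClass("Skeleton", contains = "BinaryRootMask")

#' Skeleton graph
#'
#' Undirected multigraph derived from a [Skeleton]: nodes are endpoints
#' (degree 1), junctions (degree >= 3, adjacent junction pixels merged into
#' one node), isolated pixels, and cycle anchors (one degree-2 pixel
#' promoted per pure cycle); edges are the maximal degree-2 pixel chains
#' between node pixels, carrying their geodesic length
#' (axial step = 1, diagonal step = sqrt(2), times the scale).
#'
#' @slot nodes data.frame with columns `id`, `x`, `y`, `kind`
#'   (`"endpoint"`, `"junction"`, `"isolated"`, `"cycle_anchor"`, or
#'   `"anchor"` for a chain pixel promoted to a node at the grain
#'   landmark). For merged junction clusters (x, y) is the
#'   integer-rounded centroid.
#' @slot edges data.frame with columns `u`, `v` (node ids, possibly equal
#'   for self-loops) and `length` in mm.
#' @slot chains list, one entry per edge row: an n x 2 integer matrix of
#'   (x, y) pixels from one terminal node pixel to the other, inclusive;
#'   consecutive rows are 8-neighbours.
#' @slot nodePixels list, one entry per node row: the n x 2 matrix of the
#'   node's own pixels (a junction cluster may span several).
#' @slot scale mm per pixel, inherited from the skeleton.
#'
#' @seealso [buildGraph()], [pruneSpurs()], [totalRootLength()],
#'   [longestRoot()]
#' @export
setClass("SkeletonGraph",
  representation(nodes = "data.frame", edges = "data.frame",
                 chains = "list", nodePixels = "list", scale = "numeric"))

setValidity("SkeletonGraph", function(object) {
  msg <- character()
  if (!all(c("id", "x", "y", "kind") %in% names(object@nodes)))
    msg <- c(msg, "nodes needs columns id, x, y, kind")
  if (!all(c("u", "v", "length") %in% names(object@edges)))
    msg <- c(msg, "edges needs columns u, v, length")
  if (nrow(object@edges) != length(object@chains))
    msg <- c(msg, "one chain per edge required")
  if (nrow(object@nodes) != length(object@nodePixels))
    msg <- c(msg, "one pixel set per node required")
  if (nrow(object@nodes) && !all(object@nodes$kind %in%
      c("endpoint", "junction", "isolated", "cycle_anchor", "anchor")))
    msg <- c(msg, "unknown node kind")
  if (nrow(object@edges) &&
      !all(c(object@edges$u, object@edges$v) %in% object@nodes$id))
    msg <- c(msg, "edge endpoints must be node ids")
  if (length(object@scale) != 1 || object@scale <= 0)
    msg <- c(msg, "scale must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Series manifest
#'
#' Ordered list of frames of one rhizobox time-lapse series, with
#' timestamps in hours after sowing (HAS).
#'
#' @slot entries data.frame with columns `path`, `frame_id`,
#'   `timestamp_has`, sorted by strictly increasing timestamp.
#' @slot interval capture interval in minutes (default 4, the usual
#'   time-lapse cadence; analysis often subsamples, e.g. every 10th frame
#'   giving 40-min spacing).
#'
#' @seealso [loadSeries()], [computeSeries()]
#' @export
setClass("SeriesManifest",
  representation(entries = "data.frame", interval = "numeric"))

setValidity("SeriesManifest", function(object) {
  msg <- character()
  if (!all(c("path", "frame_id", "timestamp_has") %in% names(object@entries)))
    msg <- c(msg, "entries needs columns path, frame_id, timestamp_has")
  ts <- object@entries$timestamp_has
  if (length(ts) > 1 && any(diff(ts) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (anyDuplicated(object@entries$frame_id))
    msg <- c(msg, "frame_ids must be unique")
  if (length(object@interval) != 1 || object@interval <= 0)
    msg <- c(msg, "interval must be a single positive number of minutes")
  if (length(msg)) msg else TRUE
})

#' Grain landmark and manual annotations
#'
#' Position of the sown grain, the radius of the disk around it excluded
#' from mask-derived traits (the grain body is not root), and optional
#' manual seminal-root tip overrides.
#'
#' @slot grain numeric (x, y) pixel position of the grain.
#' @slot seedExclusionRadius radius in px of the excluded disk (>= 0).
#' @slot manualTips n x 2 matrix of (x, y) tip overrides; 0 rows = none.
#'
#' @export
setClass("Landmarks",
  representation(grain = "numeric", seedExclusionRadius = "numeric",
                 manualTips = "matrix"),
  prototype(seedExclusionRadius = 10,
            manualTips = matrix(numeric(0), 0, 2)))

setValidity("Landmarks", function(object) {
  msg <- character()
  if (length(object@grain) != 2 || anyNA(object@grain))
    msg <- c(msg, "grain must be a numeric (x, y) pair")
  if (object@seedExclusionRadius < 0)
    msg <- c(msg, "seedExclusionRadius must be >= 0")
  if (ncol(object@manualTips) != 2)
    msg <- c(msg, "manualTips must have two columns (x, y)")
  if (length(msg)) msg else TRUE
})

#' Trait time series
#'
#' Per-frame trait records of one series in timestamp order, with detected
#' emergence time and the landmarks/configuration they were computed under.
#'
#' @slot records data.frame, one row per frame, columns as produced by
#'   [extractTraits()] (see [traitColumns()]).
#' @slot emergenceHAS detected emergence in hours after sowing, or `NA`
#'   when no sustained root foreground was found.
#' @slot landmarks the [Landmarks] used.
#' @slot config named list snapshot of the pipeline configuration.
#'
#' @seealso [computeSeries()], [detectEmergence()], [exportSeriesCsv()]
#' @export
setClass("TraitSeries",
  representation(records = "data.frame", emergenceHAS = "numeric",
                 landmarks = "Landmarks", config = "list"),
  prototype(emergenceHAS = NA_real_, config = list()))

setValidity("TraitSeries", function(object) {
  msg <- character()
  ts <- object@records$timestamp_has
  if (length(ts) > 1 && any(diff(ts) <= 0))
    msg <- c(msg, "record timestamps must be strictly increasing")
  e <- object@emergenceHAS
  if (length(e) != 1)
    msg <- c(msg, "emergenceHAS must be a single value (NA allowed)")
  else if (!is.na(e) && length(ts) && !any(abs(ts - e) < 1e-9))
    msg <- c(msg, "emergenceHAS must equal a record timestamp")
  if (length(msg)) msg else TRUE
})

#' Parametric root-system specification
#'
#' Deterministic description of a monocot seedling root system: one primary
#' root and further seminal roots emerging from the grain point (or
#' branching from a parent root), each with a heading, emergence time,
#' growth rate, curvature and seeded heading wobble. Together with the
#' raster geometry this fully determines every synthetic frame and its
#' analytic ground truth.
#'
#' @slot grain numeric (x, y) pixel position of the grain.
#' @slot roots data.frame, one row per root, columns `heading` (degrees
#'   from the downward vertical, positive clockwise), `emergence` (HAS),
#'   `growth_rate` (mm/h), `max_length` (mm), `curvature` (degrees per mm),
#'   `wobble_sd` (degrees per growth step), `parent` (NA or 1-based row
#'   index), `parent_pos` (mm along the parent), `parent_angle` (degrees
#'   added to the parent heading at the branch point). Row 1 is the
#'   primary root; subsequent rows are seminals in emergence order.
#' @slot strokeWidth rendered root thickness in px (>= 1).
#' @slot width,height image size in px.
#' @slot scale mm per pixel.
#' @slot seed integer RNG seed; identical seeds give bit-identical output.
#'
#' @seealso [rootSystemSpec()], [growRoots()], [rasterizeRoots()],
#'   [renderSeries()], [groundTruth()]
#' @export
setClass("RootSystemSpec",
  representation(grain = "numeric", roots = "data.frame",
                 strokeWidth = "numeric", width = "integer",
                 height = "integer", scale = "numeric", seed = "integer"))

setValidity("RootSystemSpec", function(object) {
  msg <- character()
  need <- c("heading", "emergence", "growth_rate", "max_length",
            "curvature", "wobble_sd", "parent", "parent_pos", "parent_angle")
  if (!all(need %in% names(object@roots)))
    msg <- c(msg, paste("roots needs columns:", paste(need, collapse = ", ")))
  if (length(object@grain) != 2)
    msg <- c(msg, "grain must be an (x, y) pair")
  else if (object@grain[1] < 0 || object@grain[1] > object@width - 1 ||
           object@grain[2] < 0 || object@grain[2] > object@height - 1)
    msg <- c(msg, "grain must lie inside the image")
  if (object@strokeWidth < 1)
    msg <- c(msg, "strokeWidth must be >= 1 px")
  if (nrow(object@roots)) {
    r <- object@roots
    if (any(r$growth_rate <= 0)) msg <- c(msg, "growth_rate must be > 0")
    if (any(r$emergence < 0)) msg <- c(msg, "emergence must be >= 0")
    kid <- which(!is.na(r$parent))
    for (i in kid) {
      p <- r$parent[i]
      if (p < 1 || p > nrow(r) || p == i)
        msg <- c(msg, "parent must reference another root")
      else if (r$parent_pos[i] > r$max_length[p])
        msg <- c(msg, "branch position must not exceed parent max_length")
    }
  }
  if (length(msg)) msg else TRUE
})
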