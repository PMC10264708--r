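#' Accessors for rhizotrack objects
#'
#' `maskGrid()` returns the logical pixel grid (indexed `[y + 1, x + 1]`),
#' `pixelScale()` the physical scale in mm per pixel, `graphNodes()` /
#' `graphEdges()` / `edgeChains()` the node table, edge table and pixel
#' chains of a [SkeletonGraph], `seriesRecords()` the trait table of a
#' [TraitSeries] and `emergenceTime()` its detected emergence (HAS, or
#' `NA`), and `manifestEntries()` the frame table of a [SeriesManifest].
#'
#' @param x a rhizotrack object.
#' @return See the individual descriptions above.
#' @name accessors
#' @aliases maskGrid pixelScale graphNodes graphEdges edgeChains
#'   seriesRecords emergenceTime manifestEntries
NULL

#' @rdname accessors
#' @export
setGeneric("maskGrid", function(x) standardGeneric("maskGrid"))
#' @rdname accessors
#' @export
setGeneric("pixelScale", function(x) standardGeneric("pixelScale"))
#' @rdname accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))
#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' @rdname accessors
#' @export
setGeneric("edgeChains", function(x) standardGeneric("edgeChains"))
#' @rdname accessors
#' @export
setGeneric("seriesRecords", function(x) standardGeneric("seriesRecords"))
#' @rdname accessors
#' @export
setGeneric("emergenceTime", function(x) standardGeneric("emergenceTime"))
#' @rdname accessors
#' @export
setGeneric("manifestEntries", function(x) standardGeneric("manifestEntries"))

#' @rdname accessors
setMethod("maskGrid", "BinaryRootMask", function(x) x@grid)
#' @rdname accessors
setMethod("pixelScale", "BinaryRootMask", function(x) x@scale)
#' @rdname accessors
setMethod("pixelScale", "SkeletonGraph", function(x) x@scale)
#' @rdname accessors
setMethod("graphNodes", "SkeletonGraph", function(x) x@nodes)
#' @rdname accessors
setMethod("graphEdges", "SkeletonGraph", function(x) x@edges)
#' @rdname accessors
setMethod("edgeChains", "SkeletonGraph", function(x) x@chains)
#' @rdname accessors
setMethod("seriesRecords", "TraitSeries", function(x) x@records)
#' @rdname accessors
setMethod("emergenceTime", "TraitSeries", function(x) x@emergenceHAS)
#' @rdname accessors
setMethod("manifestEntries", "SeriesManifest", function(x) x@entries)

setMethod("show", "BinaryRootMask", function(object) {
  g <- object@grid
  cat(sprintf("%s: %d x %d px, %d foreground px, scale %g mm/px\n",
              class(object), ncol(g), nrow(g), sum(g), object@scale))
})

setMethod("show", "SkeletonGraph", function(object) {
  k <- table(factor(object@nodes$kind,
                    c("endpoint", "junction", "isolated", "cycle_anchor")))
  cat(sprintf(paste0("SkeletonGraph: %d nodes (%d endpoints, %d junctions,",
                     " %d isolated, %d cycle anchors), %d edges,",
                     " total length %.3g mm\n"),
              nrow(object@nodes), k[1], k[2], k[3], k[4],
              nrow(object@edges), sum(object@edges$length)))
})

setMethod("show", "SeriesManifest", function(object) {
  e <- object@entries
  cat(sprintf("SeriesManifest: %d frames, capture interval %g min", nrow(e),
              object@interval))
  if (nrow(e))
    cat(sprintf(", %.4g-%.4g HAS", min(e$timestamp_has),
                max(e$timestamp_has)))
  cat("\n")
})

setMethod("show", "TraitSeries", function(object) {
  cat(sprintf("TraitSeries: %d records", nrow(object@records)))
  if (nrow(object@records))
    cat(sprintf(", %.4g-%.4g HAS", min(object@records$timestamp_has),
                max(object@records$timestamp_has)))
  cat(sprintf(", emergence %s\n",
              if (is.na(object@emergenceHAS)) "not detected"
              else sprintf("%.4g HAS", object@emergenceHAS)))
})

setMethod("show", "Landmarks", function(object) {
  cat(sprintf("Landmarks: grain (%g, %g), seed exclusion %g px, %d manual tips\n",
              object@grain[1], object@grain[2], object@seedExclusionRadius,
              nrow(object@manualTips)))
})

setMethod("show", "RootSystemSpec", function(object) {
  cat(sprintf(paste0("RootSystemSpec: %d roots from grain (%g, %g), %d x %d px,",
                     " stroke %g px, scale %g mm/px, seed %d\n"),
              nrow(object@roots), object@grain[1], object@grain[2],
              object@width, object@height, object@strokeWidth,
              object@scale, object@seed))
})
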