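#' Pipeline configuration
#'
#' Bundles the tunables of the trait-extraction pipeline. All defaults are
#' in pixel units and are multiplied by the mask's mm-per-pixel scale
#' where a physical quantity is needed.
#'
#' @param rule threshold rule for [binarize()] (see [thresholdRules]).
#' @param scaleMmPerPx mm per pixel (1 = report traits in pixel units).
#' @param minObjectPx foreground specks smaller than this are removed.
#' @param fillHolesMaxPx background holes smaller than this are filled.
#' @param spurMinLenPx terminal skeleton spurs shorter than this (in px;
#'   converted to mm via the scale) are pruned; suppresses 1-3 px
#'   thinning barbs without deleting lateral roots at typical stroke
#'   widths.
#' @param minAreaPx emergence threshold: root area (in px) that must be
#'   sustained for two consecutive frames.
#' @param captureIntervalMin capture interval in minutes.
#' @param startHAS timestamp of frame index 0, hours after sowing.
#' @return Named list of configuration values.
#' @export
rtConfig <- function(rule = thresholdOtsu(), scaleMmPerPx = 1,
                     minObjectPx = 5, fillHolesMaxPx = 10,
                     spurMinLenPx = 5, minAreaPx = 20,
                     captureIntervalMin = 4, startHAS = 0) {
  list(rule = rule, scale_mm_per_px = scaleMmPerPx,
       min_object_px = minObjectPx, fill_holes_max_px = fillHolesMaxPx,
       spur_min_len_px = spurMinLenPx, min_area_px = minAreaPx,
       capture_interval_min = captureIntervalMin, start_has = startHAS)
}

#' Trait record column names
#'
#' Column order of the per-frame trait table produced by [extractTraits()]
#' and exported by [exportSeriesCsv()]. Lengths are mm, areas mm^2,
#' angles degrees (pixel units when the scale is 1).
#'
#' @return Character vector of column names.
#' @export
traitColumns <- function() {
  c("frame_id", "timestamp_has", "root_area", "total_root_length",
    "longest_root_length", "primary_root_angle", "convex_hull_area",
    "bounding_box_width", "rga", "srga", "n_endpoints", "n_junctions")
}

#' Root area
#'
#' Foreground pixel count times the squared scale.
#'
#' @param mask a [BinaryRootMask].
#' @return Area in mm^2 (px^2 when the scale is 1).
#' @export
rootArea <- function(mask) {
  sum(mask@grid) * mask@scale^2
}

#' Total root system length
#'
#' Sum of the geodesic lengths of all graph edges.
#'
#' @param graph a [SkeletonGraph].
#' @return Length in mm.
#' @export
totalRootLength <- function(graph) {
  sum(graph@edges$length)
}

# pixels of a node-path through the graph, chains oriented along the walk
.pathPixels <- function(graph, nodeSeq, edgeSeq) {
  out <- NULL
  cur <- nodeSeq[1]
  for (i in seq_along(edgeSeq)) {
    e <- edgeSeq[i]
    ch <- graph@chains[[e]]
    if (graph@edges$u[e] != cur) ch <- ch[rev(seq_len(nrow(ch))), , drop = FALSE]
    if (!is.null(out) && nrow(ch) &&
        all(out[nrow(out), ] == ch[1, ])) ch <- ch[-1, , drop = FALSE]
    out <- rbind(out, ch)
    cur <- nodeSeq[i + 1]
  }
  out
}

#' Longest seed-anchored root path
#'
#' Designates the primary root: starting from the graph node nearest the
#' grain (Euclidean distance, ties by (y, x)), the maximum-geodesic-length
#' simple path to any endpoint node, found by exhaustive depth-first
#' enumeration of simple paths (skeleton graphs are small). If the start
#' node's component has no endpoint (a pure cycle), the longest simple
#' path to any node — or the cycle's self-loop — is returned instead.
#' Ties are broken by preferring more edges, then the lexicographically
#' smallest terminal (y, x).
#'
#' @param graph a non-empty [SkeletonGraph].
#' @param landmarks [Landmarks] carrying the grain position.
#' @return List with `nodes` (node id sequence), `edges` (edge row
#'   indices), `length` (mm), `pixels` (n x 2 matrix of the path's
#'   skeleton pixels) and `terminal` (last node id).
#' @export
longestRoot <- function(graph, landmarks) {
  if (!nrow(graph@edges)) stop("no root material")
  grain <- landmarks@grain
  anch <- .anchorAtGrain(graph, grain)
  graph <- anch$graph
  start <- anch$start
  n <- graph@nodes; e <- graph@edges

  incid <- vector("list", nrow(n))
  for (i in seq_len(nrow(e))) {
    incid[[e$u[i]]] <- c(incid[[e$u[i]]], i)
    if (e$v[i] != e$u[i]) incid[[e$v[i]]] <- c(incid[[e$v[i]]], i)
  }

  isEnd <- n$kind == "endpoint"
  best <- NULL  # list(len, nE, termKey, nodes, edges)
  consider <- function(len, nodeSeq, edgeSeq, toEndpoint) {
    term <- nodeSeq[length(nodeSeq)]
    cand <- list(len = len, nE = length(edgeSeq),
                 key = c(n$y[term], n$x[term]),
                 nodes = nodeSeq, edges = edgeSeq, endp = toEndpoint)
    if (is.null(best)) { best <<- cand; return(invisible()) }
    # endpoint-terminated paths dominate; then length, edges, (y,x)
    b <- best
    better <- if (cand$endp != b$endp) cand$endp else
      if (abs(cand$len - b$len) > 1e-9) cand$len > b$len else
      if (cand$nE != b$nE) cand$nE > b$nE else
      (cand$key[1] < b$key[1] ||
         (cand$key[1] == b$key[1] && cand$key[2] < b$key[2]))
    if (better) best <<- cand
    invisible()
  }

  visited <- rep(FALSE, nrow(n))
  rec <- function(cur, len, nodeSeq, edgeSeq) {
    if (length(edgeSeq))
      consider(len, nodeSeq, edgeSeq, isEnd[cur])
    for (i in incid[[cur]]) {
      nxt <- if (e$u[i] == cur) e$v[i] else e$u[i]
      if (nxt == cur) next  # self-loops are not traversed
      if (visited[nxt]) next
      visited[nxt] <<- TRUE
      rec(nxt, len + e$length[i], c(nodeSeq, nxt), c(edgeSeq, i))
      visited[nxt] <<- FALSE
    }
  }
  visited[start] <- TRUE
  rec(start, 0, start, integer(0))

  if (is.null(best)) {
    # start has only self-loops (pure cycle): take the longest one
    loops <- incid[[start]][e$u[incid[[start]]] == e$v[incid[[start]]]]
    if (!length(loops)) stop("no root material")
    i <- loops[which.max(e$length[loops])]
    best <- list(len = e$length[i], nodes = c(start, start), edges = i)
  }
  list(nodes = best$nodes, edges = best$edges, length = best$len,
       pixels = .pathPixels(graph, best$nodes, best$edges),
       terminal = best$nodes[length(best$nodes)])
}

#' Primary root angle
#'
#' Orientation of the principal axis of the primary-root skeleton pixels:
#' the dominant eigenvector of the 2 x 2 coordinate covariance matrix
#' (orthogonal regression, so near-vertical roots are not degenerate),
#' reported as the angle to the horizontal image axis in (0, 180] degrees
#' (y increases downward; a vertical root is 90 degrees).
#'
#' @param pixels n x 2 matrix of (x, y) path pixels, n >= 2 distinct.
#' @return Angle in degrees, in (0, 180].
#' @export
primaryRootAngle <- function(pixels) {
  pixels <- unique(as.matrix(pixels))
  if (nrow(pixels) < 2) stop("need at least two distinct pixels")
  cv <- stats::cov(pixels)
  v <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  ang <- (atan2(v[2], v[1]) * 180 / pi) %% 180
  if (ang <= 1e-12) ang <- 180
  ang
}

# polygon area by the shoelace formula; vertices as n x 2 matrix
.shoelace <- function(p) {
  n <- nrow(p)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

#' Convex hull area of the root system
#'
#' Area of the convex hull of the foreground pixel centers (shoelace
#' formula), times the squared scale. Collinear or singleton foregrounds
#' return 0.
#'
#' @param mask a [BinaryRootMask] with at least one foreground pixel.
#' @return Area in mm^2.
#' @export
convexHullArea <- function(mask) {
  px <- .maskPixels(mask@grid)
  if (!nrow(px)) stop("empty mask has no convex hull")
  h <- grDevices::chull(px[, 1], px[, 2])
  .shoelace(px[h, , drop = FALSE]) * mask@scale^2
}

#' Bounding-box width of the root system
#'
#' Axis-aligned inclusive pixel extent: `(max_x - min_x + 1) * scale`,
#' the maximum root system width.
#'
#' @param mask a [BinaryRootMask] with at least one foreground pixel.
#' @return Width in mm.
#' @export
boundingBoxWidth <- function(mask) {
  px <- .maskPixels(mask@grid)
  if (!nrow(px)) stop("empty mask has no bounding box")
  (max(px[, 1]) - min(px[, 1]) + 1) * mask@scale
}

# per-endpoint best simple path from a component-local start node:
# length and first edge; used for tip partitioning
.endpointPaths <- function(graph, grain) {
  graph <- .anchorAtGrain(graph, grain)$graph
  n <- graph@nodes; e <- graph@edges
  comp <- .graphComponents(graph)
  res <- list()
  incid <- vector("list", nrow(n))
  for (i in seq_len(nrow(e))) {
    incid[[e$u[i]]] <- c(incid[[e$u[i]]], i)
    if (e$v[i] != e$u[i]) incid[[e$v[i]]] <- c(incid[[e$v[i]]], i)
  }
  # distance from the grain to a node's nearest own pixel
  nodeDist <- vapply(seq_len(nrow(n)), function(i) {
    p <- graph@nodePixels[[i]]
    min(sqrt((p[, 1] - grain[1])^2 + (p[, 2] - grain[2])^2))
  }, numeric(1))
  for (cc in unique(comp)) {
    ids <- n$id[comp == cc]
    ord <- order(nodeDist[ids], n$y[ids], n$x[ids])
    start <- ids[ord[1]]
    visited <- rep(FALSE, nrow(n))
    visited[start] <- TRUE
    rec <- function(cur, len, firstEdge) {
      if (n$kind[cur] == "endpoint" && !is.na(firstEdge)) {
        key <- as.character(cur)
        old <- res[[key]]
        if (is.null(old) || len > old$len + 1e-9)
          res[[key]] <<- list(node = cur, len = len,
                              part = paste0(cc, ":", firstEdge))
      }
      for (i in incid[[cur]]) {
        nxt <- if (e$u[i] == cur) e$v[i] else e$u[i]
        if (nxt == cur || visited[nxt]) next
        visited[nxt] <<- TRUE
        rec(nxt, len + e$length[i], if (is.na(firstEdge)) i else firstEdge)
        visited[nxt] <<- FALSE
      }
    }
    rec(start, 0, NA_integer_)
  }
  res
}

#' Seminal root tips
#'
#' Returns `k` seminal-root tip positions. Manual tip overrides on the
#' landmarks are returned verbatim. Otherwise endpoint nodes are
#' partitioned by the first edge leaving their component's grain-nearest
#' start node on their (maximum-length simple) path; the `k` partitions
#' with greatest path length each contribute their farthest-from-grain
#' endpoint, ordered by descending path length. Ties are broken by (y, x).
#'
#' @param graph a [SkeletonGraph] with at least `k` endpoint nodes.
#' @param landmarks [Landmarks] with the grain position.
#' @param k number of tips (>= 2 for angle traits).
#' @return k x 2 matrix of (x, y) tip positions.
#' @export
seminalTips <- function(graph, landmarks, k = 2) {
  if (nrow(landmarks@manualTips)) return(landmarks@manualTips)
  n <- graph@nodes
  nEnd <- sum(n$kind == "endpoint")
  if (nEnd < k) stop("fewer than ", k, " endpoints in the skeleton graph")
  paths <- .endpointPaths(graph, landmarks@grain)
  if (!length(paths)) stop("no grain-anchored root branches found")
  tab <- do.call(rbind, lapply(paths, function(p)
    data.frame(node = p$node, len = p$len, part = p$part,
               stringsAsFactors = FALSE)))
  parts <- split(tab, tab$part)
  repLen <- vapply(parts, function(p) max(p$len), numeric(1))
  if (length(parts) < k)
    stop("fewer than ", k, " distinct root branches from the grain")
  grain <- landmarks@grain
  ord <- order(-repLen)
  sel <- parts[ord[seq_len(k)]]
  tips <- t(vapply(sel, function(p) {
    xy <- cbind(n$x[p$node], n$y[p$node])
    d <- sqrt((xy[, 1] - grain[1])^2 + (xy[, 2] - grain[2])^2)
    i <- order(-d, xy[, 2], xy[, 1])[1]
    c(xy[i, 1], xy[i, 2])
  }, numeric(2)))
  dimnames(tips) <- NULL
  tips
}

#' Root growth angle (RGA)
#'
#' Angle between the horizontal line through the grain and the line from
#' the grain to the most distant tip, as a protractor-style reading in
#' [0, 90] degrees: `atan(|dy| / |dx|)`, with a tip straight below (or
#' above) the grain giving 90 degrees.
#'
#' @param landmarks [Landmarks] with the grain position.
#' @param tips n x 2 matrix of candidate (x, y) tips; the farthest from
#'   the grain defines the angle.
#' @return Angle in degrees, in [0, 90].
#' @export
rga <- function(landmarks, tips) {
  tips <- matrix(as.numeric(tips), ncol = 2)
  if (!nrow(tips)) stop("no tips given")
  grain <- landmarks@grain
  d <- sqrt((tips[, 1] - grain[1])^2 + (tips[, 2] - grain[2])^2)
  i <- order(-d, tips[, 2], tips[, 1])[1]
  if (d[i] == 0) stop("tip coincides with the grain")
  dx <- abs(tips[i, 1] - grain[1]); dy <- abs(tips[i, 2] - grain[2])
  if (dx == 0) 90 else atan(dy / dx) * 180 / pi
}

#' Seminal root growth angle (SRGA)
#'
#' Angle at the grain between the lines to the first two seminal root
#' tips, via the arccosine of the normalized dot product, in [0, 180]
#' degrees.
#'
#' @param landmarks [Landmarks] with the grain position.
#' @param tip1,tip2 (x, y) tip positions, both distinct from the grain.
#' @return Angle in degrees, in [0, 180].
#' @export
srga <- function(landmarks, tip1, tip2) {
  grain <- landmarks@grain
  v1 <- as.numeric(tip1) - grain; v2 <- as.numeric(tip2) - grain
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("tip coincides with the grain")
  acos(max(-1, min(1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}

# all-zero trait record with absent angles
.zeroRecord <- function(frameId, timestampHAS) {
  data.frame(frame_id = frameId, timestamp_has = timestampHAS,
             root_area = 0, total_root_length = 0, longest_root_length = 0,
             primary_root_angle = NA_real_, convex_hull_area = 0,
             bounding_box_width = 0, rga = NA_real_, srga = NA_real_,
             n_endpoints = 0L, n_junctions = 0L)
}

#' Extract all root-system traits from one frame's mask
#'
#' Orchestrates the per-frame pipeline: mask cleaning, removal of the
#' seed-exclusion disk around the grain (the grain body is not root),
#' skeletonization, graph construction, spur pruning, and every trait.
#' Frames without root material yield an all-zero record with absent
#' angles; trait-level failures (e.g. too few branches for the seminal
#' angle) become absent values rather than errors.
#'
#' @param mask a [BinaryRootMask].
#' @param landmarks [Landmarks] (grain, seed-exclusion radius, optional
#'   manual tips).
#' @param config configuration list from [rtConfig()].
#' @param frameId,timestampHAS frame identity recorded in the output row.
#' @return One-row data.frame with columns [traitColumns()].
#' @export
extractTraits <- function(mask, landmarks, config = rtConfig(),
                          frameId = NA_integer_, timestampHAS = NA_real_) {
  m <- cleanMask(mask, config$min_object_px, config$fill_holes_max_px)
  r <- landmarks@seedExclusionRadius
  if (r > 0) {
    g <- m@grid
    xs <- matrix(0:(ncol(g) - 1), nrow(g), ncol(g), byrow = TRUE)
    ys <- matrix(0:(nrow(g) - 1), nrow(g), ncol(g))
    g[(xs - landmarks@grain[1])^2 + (ys - landmarks@grain[2])^2 <= r^2] <- FALSE
    m <- binaryRootMask(g, m@scale)
  }
  if (!any(m@grid)) return(.zeroRecord(frameId, timestampHAS))

  sk <- skeletonize(m)
  gr <- buildGraph(sk)
  gr <- pruneSpurs(gr, config$spur_min_len_px * m@scale)

  total <- totalRootLength(gr)
  lr <- tryCatch(longestRoot(gr, landmarks), error = function(e) NULL)
  ang <- if (!is.null(lr) && !is.null(lr$pixels) && nrow(lr$pixels) >= 2)
    tryCatch(primaryRootAngle(lr$pixels), error = function(e) NA_real_)
  else NA_real_

  nd <- gr@nodes
  endTips <- cbind(nd$x[nd$kind == "endpoint"], nd$y[nd$kind == "endpoint"])
  rgaTips <- if (nrow(landmarks@manualTips)) landmarks@manualTips else endTips
  rgaV <- tryCatch(rga(landmarks, rgaTips), error = function(e) NA_real_)
  tips <- tryCatch(seminalTips(gr, landmarks, 2), error = function(e) NULL)
  srgaV <- if (is.null(tips)) NA_real_ else
    tryCatch(srga(landmarks, tips[1, ], tips[2, ]), error = function(e) NA_real_)

  data.frame(frame_id = frameId, timestamp_has = timestampHAS,
             root_area = rootArea(m),
             total_root_length = total,
             longest_root_length = if (is.null(lr)) 0 else lr$length,
             primary_root_angle = ang,
             convex_hull_area = convexHullArea(m),
             bounding_box_width = boundingBoxWidth(m),
             rga = rgaV, srga = srgaV,
             n_endpoints = sum(nd$kind == "endpoint"),
             n_junctions = sum(nd$kind == "junction"))
}

#' Render a QC overlay image
#'
#' Writes a PNG with the mask in gray, the skeleton in green, the longest
#' (primary) root path in red, the convex hull vertices in blue and the
#' grain in yellow, for visual checking of a frame's analysis.
#'
#' @param mask a [BinaryRootMask].
#' @param path output PNG path.
#' @param graph optional [SkeletonGraph] of the frame.
#' @param primaryPath optional path object from [longestRoot()].
#' @param landmarks optional [Landmarks].
#' @return `path`, invisibly.
#' @export
renderOverlay <- function(mask, path, graph = NULL, primaryPath = NULL,
                          landmarks = NULL) {
  g <- mask@grid
  H <- nrow(g); W <- ncol(g)
  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) img[, , ch][g] <- 0.35
  put <- function(px, col) {
    px <- px[px[, 1] >= 0 & px[, 1] < W & px[, 2] >= 0 & px[, 2] < H, ,
             drop = FALSE]
    idx <- cbind(px[, 2] + 1, px[, 1] + 1)
    for (ch in 1:3) {
      m2 <- img[, , ch]; m2[idx] <- col[ch]; img[, , ch] <<- m2
    }
  }
  if (!is.null(graph))
    for (chn in graph@chains) put(chn, c(0, 1, 0))
  px <- .maskPixels(g)
  if (nrow(px) >= 3)
    put(px[grDevices::chull(px[, 1], px[, 2]), , drop = FALSE], c(0.2, 0.4, 1))
  if (!is.null(primaryPath) && !is.null(primaryPath$pixels))
    put(primaryPath$pixels, c(1, 0, 0))
  if (!is.null(landmarks))
    put(matrix(round(landmarks@grain), 1), c(1, 1, 0))
  png::writePNG(img, path)
  invisible(path)
}
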