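# run expr under a private RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Describe one synthetic root
#'
#' One row of the root table of a [RootSystemSpec]. Headings are degrees
#' from the downward vertical (positive clockwise, i.e. toward +x);
#' growth is linear at `growthRate` mm/h from `emergence` (hours after
#' sowing) until `maxLength` mm; `curvature` bends the heading by a fixed
#' number of degrees per mm grown and `wobbleSd` adds seeded Gaussian
#' heading noise (degrees per 1-px growth step). A root may branch from a
#' parent root at arc position `parentPos` mm, taking the parent's local
#' heading plus `parentAngle` degrees (its own `heading` is then
#' ignored); the parent must appear earlier in the table.
#'
#' @param heading degrees from downward vertical, positive clockwise.
#' @param emergence hours after sowing (default 64, the typical first
#'   observation of a root in rhizobox series).
#' @param growthRate mm per hour (> 0); default 1.2, a realistic seedling
#'   elongation rate.
#' @param maxLength cap in mm.
#' @param curvature degrees per mm.
#' @param wobbleSd degrees of heading noise per growth step.
#' @param parent NA or 1-based index of the parent root.
#' @param parentPos arc position of the branch point on the parent, mm.
#' @param parentAngle degrees added to the parent heading at the branch.
#' @return One-row data.frame.
#' @export
rootSpec <- function(heading, emergence = 64, growthRate = 1.2,
                     maxLength = 20, curvature = 0, wobbleSd = 0,
                     parent = NA_integer_, parentPos = NA_real_,
                     parentAngle = NA_real_) {
  data.frame(heading = heading, emergence = emergence,
             growth_rate = growthRate, max_length = maxLength,
             curvature = curvature, wobble_sd = wobbleSd,
             parent = as.integer(parent), parent_pos = parentPos,
             parent_angle = parentAngle)
}

#' Assemble a root-system specification
#'
#' @param grain (x, y) pixel position of the grain.
#' @param roots data.frame of stacked [rootSpec()] rows; row 1 is the
#'   primary root, later rows seminals in emergence order.
#' @param strokeWidth rendered root thickness in px.
#' @param width,height image size in px.
#' @param scale mm per pixel (default 0.1, i.e. 10 px per mm, a typical
#'   close-up rhizobox calibration).
#' @param seed integer RNG seed; everything downstream is deterministic
#'   in it.
#' @return A [RootSystemSpec].
#' @export
rootSystemSpec <- function(grain, roots, strokeWidth = 3, width = 400L,
                           height = 260L, scale = 0.1, seed = 1L) {
  new("RootSystemSpec", grain = as.numeric(grain), roots = roots,
      strokeWidth = strokeWidth, width = as.integer(width),
      height = as.integer(height), scale = scale, seed = as.integer(seed))
}

# full deterministic geometry of every root at maximum length:
# per root a list(verts [n x 2 px incl. origin], headings [deg per step])
.rootGeometry <- function(spec) {
  roots <- spec@roots
  scale <- spec@scale
  dsPx <- 1
  dsMm <- dsPx * scale
  geo <- vector("list", nrow(roots))
  for (i in seq_len(nrow(roots))) {
    r <- roots[i, ]
    nSteps <- max(1L, ceiling(r$max_length / dsMm))
    wob <- if (r$wobble_sd > 0)
      .withSeed(spec@seed + 7919L * i, stats::rnorm(nSteps, 0, r$wobble_sd))
    else rep(0, nSteps)
    if (is.na(r$parent)) {
      origin <- spec@grain
      h0 <- r$heading
    } else {
      p <- geo[[r$parent]]
      if (is.null(p)) stop("parent roots must precede their children")
      sAt <- min(r$parent_pos, roots$max_length[r$parent])
      k <- min(length(p$headings), max(1L, ceiling(sAt / dsMm)))
      frac <- sAt / dsMm - (k - 1)
      origin <- p$verts[k, ] + pmin(pmax(frac, 0), 1) *
        (p$verts[k + 1, ] - p$verts[k, ])
      h0 <- p$headings[k] + r$parent_angle
    }
    headings <- h0 + r$curvature * dsMm * (seq_len(nSteps) - 1) +
      cumsum(wob) - wob  # wobble accumulated before each step
    rad <- headings * pi / 180
    steps <- cbind(sin(rad), cos(rad)) * dsPx
    verts <- rbind(origin, cbind(origin[1] + cumsum(steps[, 1]),
                                 origin[2] + cumsum(steps[, 2])))
    geo[[i]] <- list(verts = unname(verts), headings = headings)
  }
  geo
}

# polyline of root i truncated to arc length lenMm (px coordinates)
.truncatePolyline <- function(g, lenMm, scale) {
  dsMm <- scale
  if (lenMm <= 0) return(NULL)
  nFull <- floor(lenMm / dsMm + 1e-9)
  nFull <- min(nFull, nrow(g$verts) - 1L)
  v <- g$verts[seq_len(nFull + 1L), , drop = FALSE]
  frac <- lenMm / dsMm - nFull
  if (frac > 1e-9 && nFull + 1L < nrow(g$verts)) {
    extra <- g$verts[nFull + 1L, ] +
      frac * (g$verts[nFull + 2L, ] - g$verts[nFull + 1L, ])
    v <- rbind(v, extra)
  }
  v
}

#' Grow the root-system centerlines to a time point
#'
#' Each root is traced from its origin (grain or parent branch point)
#' along its heading with curvature and seeded wobble, to arc length
#' `growth_rate * max(0, t - emergence)` capped at `max_length`. Output
#' is identical for identical seeds.
#'
#' @param spec a [RootSystemSpec].
#' @param t hours after sowing (>= 0).
#' @return Named list of n x 2 polyline vertex matrices in pixel
#'   coordinates, one per root with positive length (names are root
#'   indices); roots not yet emerged are absent.
#' @export
growRoots <- function(spec, t) {
  roots <- spec@roots
  geo <- .rootGeometry(spec)
  lens <- pmin(roots$growth_rate * pmax(0, t - roots$emergence),
               roots$max_length)
  out <- list()
  for (i in seq_len(nrow(roots))) {
    if (lens[i] <= 0) next
    out[[as.character(i)]] <- .truncatePolyline(geo[[i]], lens[i], spec@scale)
  }
  out
}

#' Analytic ground truth of a root system at a time point
#'
#' Everything the trait pipeline is supposed to recover, computed from
#' the centerline geometry: per-root arc lengths and tip positions, total
#' length, the angle between the first two grain-anchored roots (SRGA),
#' convex hull area and bounding-box width of the centerline vertices,
#' and emergence times.
#'
#' Two derived conveniences support validation against the pixel-based
#' measurement. `total_length_digital_mm` re-expresses the centerline
#' length in the geodesic pixel metric the skeleton traits use (per unit
#' step of direction (dx, dy): `max + (sqrt(2) - 1) * min` of the
#' absolute components), which for oblique lines exceeds Euclidean length
#' by up to ~8%; a skeleton measurement should be compared against this,
#' plus half a stroke width per free root end for the rasterizer's
#' protruding end caps. `hull_area_inflated_mm2` and
#' `bbox_width_inflated_mm` inflate the centerline hull/extent by the
#' stroke: the hull by Minkowski radius `(strokeWidth - 1) / 2` px
#' (mask hulls are taken over pixel centers), the width by a full
#' `strokeWidth` (the measured width is an inclusive pixel extent).
#'
#' @param spec a [RootSystemSpec].
#' @param t hours after sowing.
#' @return Named list; lengths in mm, areas in mm^2, angles in degrees,
#'   tips in px coordinates.
#' @export
groundTruth <- function(spec, t) {
  roots <- spec@roots
  scale <- spec@scale
  poly <- growRoots(spec, t)
  lens <- pmin(roots$growth_rate * pmax(0, t - roots$emergence),
               roots$max_length)
  lens[lens < 0] <- 0
  tips <- matrix(NA_real_, nrow(roots), 2)
  for (nm in names(poly)) {
    i <- as.integer(nm)
    tips[i, ] <- poly[[nm]][nrow(poly[[nm]]), ]
  }
  srgaDeg <- NA_real_
  anchored <- which(is.na(roots$parent))
  emerged <- anchored[lens[anchored] > 0]
  if (length(emerged) >= 2) {
    i1 <- emerged[1]; i2 <- emerged[2]
    v1 <- tips[i1, ] - spec@grain; v2 <- tips[i2, ] - spec@grain
    srgaDeg <- acos(max(-1, min(1, sum(v1 * v2) /
      (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
  }
  digital <- 0
  for (pl in poly) {
    if (nrow(pl) < 2) next
    dx <- abs(diff(pl[, 1])); dy <- abs(diff(pl[, 2]))
    digital <- digital +
      sum(pmax(dx, dy) + (sqrt(2) - 1) * pmin(dx, dy)) * scale
  }
  verts <- do.call(rbind, poly)
  hull <- 0; bbw <- 0; hullInf <- 0; bbwInf <- 0
  rMm <- (spec@strokeWidth - 1) / 2 * scale
  if (!is.null(verts) && nrow(verts) >= 1) {
    h <- grDevices::chull(verts[, 1], verts[, 2])
    hp <- verts[h, , drop = FALSE]
    hull <- .shoelace(hp) * scale^2
    per <- if (nrow(hp) >= 2)
      sum(sqrt(rowSums((hp - hp[c(2:nrow(hp), 1), , drop = FALSE])^2))) *
        scale else 0
    hullInf <- hull + per * rMm + pi * rMm^2
    bbw <- (max(verts[, 1]) - min(verts[, 1])) * scale
    bbwInf <- bbw + spec@strokeWidth * scale
  }
  list(t_has = t, lengths_mm = lens, tips_px = tips,
       total_length_mm = sum(lens),
       total_length_digital_mm = digital, srga_deg = srgaDeg,
       hull_area_mm2 = hull, hull_area_inflated_mm2 = hullInf,
       bbox_width_mm = bbw, bbox_width_inflated_mm = bbwInf,
       emergence_has = roots$emergence,
       system_emergence_has = min(roots$emergence))
}

#' Rasterize centerline polylines into a binary mask
#'
#' The mask is the union of disks of radius `strokeWidth / 2` swept along
#' the polylines: a pixel is foreground iff its center lies within that
#' distance of some polyline segment. Geometry leaving the canvas is
#' clipped and flagged via `attr(mask, "clipped")`.
#'
#' @param polylines list of n x 2 vertex matrices in px coordinates (as
#'   from [growRoots()]).
#' @param strokeWidth stroke thickness in px (>= 1).
#' @param width,height canvas size in px.
#' @param scale mm per pixel recorded on the mask.
#' @return A [BinaryRootMask].
#' @export
rasterizeRoots <- function(polylines, strokeWidth, width, height,
                           scale = 1) {
  stopifnot(strokeWidth >= 1)
  g <- matrix(FALSE, height, width)
  r <- strokeWidth / 2
  clipped <- FALSE
  for (pl in polylines) {
    if (is.null(pl) || nrow(pl) < 1) next
    if (any(pl[, 1] < 0 | pl[, 1] > width - 1 |
            pl[, 2] < 0 | pl[, 2] > height - 1)) clipped <- TRUE
    nseg <- nrow(pl) - 1L
    for (s in seq_len(max(nseg, 0L))) {
      a <- pl[s, ]; b <- pl[s + 1L, ]
      x0 <- max(0L, floor(min(a[1], b[1]) - r))
      x1 <- min(width - 1L, ceiling(max(a[1], b[1]) + r))
      y0 <- max(0L, floor(min(a[2], b[2]) - r))
      y1 <- min(height - 1L, ceiling(max(a[2], b[2]) + r))
      if (x1 < x0 || y1 < y0) next
      xs <- x0:x1; ys <- y0:y1
      px <- matrix(xs, length(ys), length(xs), byrow = TRUE)
      py <- matrix(ys, length(ys), length(xs))
      ab <- b - a
      len2 <- sum(ab^2)
      if (len2 == 0) {
        d2 <- (px - a[1])^2 + (py - a[2])^2
      } else {
        tt <- ((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2
        tt <- pmin(pmax(tt, 0), 1)
        d2 <- (px - (a[1] + tt * ab[1]))^2 + (py - (a[2] + tt * ab[2]))^2
      }
      sub <- g[ys + 1L, xs + 1L, drop = FALSE]
      g[ys + 1L, xs + 1L] <- sub | (d2 <= r^2)
    }
  }
  mask <- binaryRootMask(g, scale)
  attr(mask, "clipped") <- clipped
  mask
}

#' Render a synthetic frame sequence to disk
#'
#' Writes PNG frames at a fixed cadence together with per-frame ground
#' truth and a manifest CSV. Frames are taken at
#' `startHAS + 0, interval, 2 interval, ...` up to and including
#' `startHAS + duration`. Identical specs and seeds give byte-identical
#' frames.
#'
#' @param spec a [RootSystemSpec].
#' @param intervalMin frame spacing in minutes (e.g. 4 for the native
#'   capture cadence, 40 for an every-10th-frame analysis series).
#' @param durationH covered time span in hours (> 0).
#' @param dir output directory (created if needed).
#' @param startHAS time of the first frame, hours after sowing.
#' @return List with `manifest` (a [SeriesManifest]) and `groundTruth`
#'   (list of [groundTruth()] results, one per frame). The directory
#'   additionally receives `manifest.csv` and `ground_truth.json`.
#' @export
renderSeries <- function(spec, intervalMin = 40, durationH, dir,
                         startHAS = 0) {
  stopifnot(durationH > 0)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tMin <- seq(0, durationH * 60, by = intervalMin)
  times <- startHAS + tMin / 60
  gt <- vector("list", length(times))
  paths <- character(length(times))
  for (i in seq_along(times)) {
    poly <- growRoots(spec, times[i])
    mask <- rasterizeRoots(poly, spec@strokeWidth, spec@width,
                           spec@height, spec@scale)
    paths[i] <- file.path(dir, sprintf("frame_%05d.png", i - 1L))
    writeMaskPng(mask, paths[i])
    gt[[i]] <- groundTruth(spec, times[i])
  }
  entries <- data.frame(path = paths, frame_id = seq_along(times) - 1L,
                        timestamp_has = times, stringsAsFactors = FALSE)
  manifest <- new("SeriesManifest", entries = entries,
                  interval = intervalMin)
  utils::write.csv(entries, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  list(manifest = manifest, groundTruth = gt)
}

#' Genotype-style demo presets
#'
#' Two-seminal root systems echoing contrasting seminal-root-angle
#' genotypes: `"GP-like"` spreads the first two seminal roots 109.3
#' degrees apart, `"BCC93-like"` 62.7 degrees. Headings are symmetric
#' about the vertical; `headingNoiseSd` adds seeded Gaussian noise to
#' each heading independently, emulating between-replicate variation.
#' The two roots emerge at 64 and 66 HAS and grow 1.2 mm/h to 20 mm.
#'
#' @param name `"GP-like"` or `"BCC93-like"`.
#' @param seed integer seed (drives heading noise and wobble).
#' @param headingNoiseSd per-root heading noise in degrees.
#' @param wobbleSd within-root heading wobble, degrees per step.
#' @param grain,width,height,scale,strokeWidth raster geometry, see
#'   [rootSystemSpec()].
#' @return A [RootSystemSpec].
#' @export
genotypePreset <- function(name = c("GP-like", "BCC93-like"), seed = 1L,
                           headingNoiseSd = 0, wobbleSd = 0.2,
                           grain = c(200, 20), width = 400L,
                           height = 260L, scale = 0.1, strokeWidth = 3) {
  name <- match.arg(name)
  spread <- if (name == "GP-like") 109.3 else 62.7
  h <- c(-spread / 2, spread / 2)
  if (headingNoiseSd > 0)
    h <- h + .withSeed(seed + 104729L,
                       stats::rnorm(2, 0, headingNoiseSd))
  roots <- rbind(
    rootSpec(heading = h[1], emergence = 64, growthRate = 1.2,
             maxLength = 20, wobbleSd = wobbleSd),
    rootSpec(heading = h[2], emergence = 66, growthRate = 1.2,
             maxLength = 20, wobbleSd = wobbleSd))
  rootSystemSpec(grain = grain, roots = roots, strokeWidth = strokeWidth,
                 width = width, height = height, scale = scale,
                 seed = seed)
}
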