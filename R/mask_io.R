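#' Construct a binary root mask
#'
#' @param grid logical matrix (`TRUE` = root foreground), indexed
#'   `[y + 1, x + 1]` with 0-based pixel coordinates x rightward and
#'   y downward.
#' @param scale mm per pixel; the default 1 reports traits in pixel units.
#' @return A [BinaryRootMask].
#' @export
binaryRootMask <- function(grid, scale = 1) {
  storage.mode(grid) <- "logical"
  new("BinaryRootMask", grid = grid, scale = scale)
}

#' Construct grain landmarks
#'
#' @param grain numeric (x, y) pixel position of the sown grain.
#' @param seedExclusionRadius radius (px) of the disk around the grain
#'   excluded from mask-derived traits; the grain body is not root.
#' @param manualTips optional n x 2 matrix of (x, y) seminal-tip overrides.
#' @return A [Landmarks] object.
#' @export
landmarks <- function(grain, seedExclusionRadius = 10, manualTips = NULL) {
  if (is.null(manualTips)) manualTips <- matrix(numeric(0), 0, 2)
  manualTips <- as.matrix(manualTips)
  new("Landmarks", grain = as.numeric(grain),
      seedExclusionRadius = seedExclusionRadius, manualTips = manualTips)
}

#' Read one raster frame
#'
#' Reads a PNG or TIFF frame into an integer intensity array in 0-255:
#' a matrix for grayscale input, an H x W x 3 array for RGB (an alpha
#' channel, if present, is dropped).
#'
#' @param path file path; format chosen by extension (.png/.tif/.tiff).
#' @return Integer matrix or H x W x 3 array of intensities in 0-255.
#' @export
readFrame <- function(path) {
  if (!file.exists(path)) stop("no such frame: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: .", ext, " (", path, ")"))
  if (length(dim(img)) == 3) {
    if (dim(img)[3] >= 3) img <- img[, , 1:3, drop = FALSE]
    else img <- img[, , 1]
  }
  storage.mode(img) <- "double"
  arr <- round(img * 255)
  storage.mode(arr) <- "integer"
  arr
}

.frameChannel <- function(frame, channel) {
  d <- dim(frame)
  nch <- if (length(d) == 3) d[3] else 1L
  if (channel == "gray") {
    if (nch == 1) return(frame)
    return((frame[, , 1] + frame[, , 2] + frame[, , 3]) / 3)
  }
  idx <- match(channel, c("r", "g", "b"))
  if (is.na(idx)) stop("unknown channel: ", channel)
  if (nch != 3)
    stop("rule references channel '", channel,
         "' but the frame has no color channels")
  frame[, , idx]
}

#' Threshold rules for binarization
#'
#' Three rules cover the usual inputs: `thresholdFixed()` marks pixels
#' whose intensity on one channel exceeds (or falls below) a fixed cut;
#' `thresholdBox()` keeps pixels inside a per-channel min/max color box,
#' the natural rule for manually traced color overlays (e.g. a pure-red
#' stylus trace over a grayscale photograph); `thresholdOtsu()` picks a
#' global cut on a grayscale channel automatically by maximizing the
#' between-class intensity variance over the 256-bin histogram.
#'
#' @param value intensity cut in 0-255.
#' @param channel `"gray"` (mean of RGB for color frames) or `"r"`,
#'   `"g"`, `"b"`.
#' @param above if `TRUE` (default) foreground is intensity > value,
#'   otherwise intensity < value.
#' @param rmin,rmax,gmin,gmax,bmin,bmax inclusive channel bounds in 0-255.
#' @param dark if `TRUE` foreground is the class below the automatic cut
#'   (dark roots on a bright background); default `FALSE`.
#' @return A threshold rule object for [binarize()].
#' @name thresholdRules
NULL

#' @rdname thresholdRules
#' @export
thresholdFixed <- function(value, channel = "gray", above = TRUE) {
  structure(list(type = "fixed", value = value, channel = channel,
                 above = above), class = "threshold_rule")
}

#' @rdname thresholdRules
#' @export
thresholdBox <- function(rmin = 0, rmax = 255, gmin = 0, gmax = 255,
                         bmin = 0, bmax = 255) {
  structure(list(type = "box", rmin = rmin, rmax = rmax, gmin = gmin,
                 gmax = gmax, bmin = bmin, bmax = bmax),
            class = "threshold_rule")
}

#' @rdname thresholdRules
#' @export
thresholdOtsu <- function(channel = "gray", dark = FALSE) {
  structure(list(type = "otsu", channel = channel, dark = dark),
            class = "threshold_rule")
}

# Otsu's cut on 0-255 intensities: threshold t maximizing the
# between-class variance w0*w1*(mu0-mu1)^2; foreground is > t. The
# variance is flat between well-separated modes, so the midpoint of the
# maximizing plateau is taken (deterministic and mode-symmetric).
.otsuCut <- function(intens) {
  h <- tabulate(as.integer(intens) + 1L, nbins = 256L)
  n <- sum(h)
  lev <- 0:255
  w0 <- cumsum(h)
  m0 <- cumsum(h * lev)
  mt <- m0[256]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, 256)
  bcv[valid] <- (mt * w0[valid] - n * m0[valid])^2 /
    (as.numeric(w0[valid]) * w1[valid])
  best <- which(bcv >= max(bcv) - 1e-9)
  lev[floor(mean(range(best)))]
}

#' Binarize a frame into a root mask
#'
#' Applies a threshold rule (see [thresholdRules]) pixel-wise; a pixel is
#' foreground iff it satisfies the rule. Output shape equals the input
#' frame.
#'
#' @param frame intensity array as returned by [readFrame()] (or a path,
#'   which is read first).
#' @param rule a rule from [thresholdFixed()], [thresholdBox()] or
#'   [thresholdOtsu()].
#' @param scale mm per pixel recorded on the resulting mask.
#' @return A [BinaryRootMask].
#' @export
binarize <- function(frame, rule, scale = 1) {
  if (is.character(frame)) frame <- readFrame(frame)
  stopifnot(inherits(rule, "threshold_rule"))
  grid <- switch(rule$type,
    fixed = {
      ch <- .frameChannel(frame, rule$channel)
      if (rule$above) ch > rule$value else ch < rule$value
    },
    box = {
      d <- dim(frame)
      if (length(d) != 3 || d[3] != 3)
        stop("color-box rule requires an RGB frame")
      frame[, , 1] >= rule$rmin & frame[, , 1] <= rule$rmax &
        frame[, , 2] >= rule$gmin & frame[, , 2] <= rule$gmax &
        frame[, , 3] >= rule$bmin & frame[, , 3] <= rule$bmax
    },
    otsu = {
      ch <- .frameChannel(frame, rule$channel)
      cut <- .otsuCut(ch)
      if (rule$dark) ch < cut else ch > cut
    },
    stop("unknown threshold rule type: ", rule$type))
  dim(grid) <- dim(frame)[1:2]
  binaryRootMask(grid, scale)
}

#' Clean a binary root mask
#'
#' Removes 8-connected foreground specks smaller than `minObjectPx` and
#' fills 4-connected background holes smaller than `fillHolesMaxPx`; all
#' other pixels are unchanged. Holes are background components that do not
#' touch the image border. The operation is idempotent.
#'
#' @param mask a [BinaryRootMask].
#' @param minObjectPx components with fewer pixels than this are removed.
#' @param fillHolesMaxPx holes with fewer pixels than this are filled.
#' @return The cleaned [BinaryRootMask].
#' @export
cleanMask <- function(mask, minObjectPx = 0, fillHolesMaxPx = 0) {
  g <- mask@grid
  if (minObjectPx > 0 && any(g)) {
    lab <- .label_cc(g, TRUE)
    sz <- tabulate(lab[lab > 0])
    g[lab > 0 & sz[pmax(lab, 1)] < minObjectPx] <- FALSE
  }
  if (fillHolesMaxPx > 0 && any(!g)) {
    lab <- .label_cc(!g, FALSE)
    if (max(lab) > 0) {
      border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                         lab[, ncol(lab)]))
      border <- border[border > 0]
      sz <- tabulate(lab[lab > 0])
      fill <- setdiff(which(sz < fillHolesMaxPx), border)
      g[lab %in% fill] <- TRUE
    }
  }
  binaryRootMask(g, mask@scale)
}

#' Build or load a series manifest
#'
#' From a directory of frames, timestamps are derived from a frame index
#' embedded in each filename: `pattern` is a regular expression whose
#' first capture group is the integer index, and
#' `timestamp = startHAS + index * interval / 60` hours after sowing.
#' Alternatively `source` may be a manifest CSV with columns
#' `path`, `frame_id`, `timestamp_has` giving explicit timestamps (the
#' natural form for subsampled series, e.g. every 10th frame of a 4-min
#' capture, spaced 40 min apart).
#'
#' @param source directory containing the frames, or path to a manifest
#'   CSV file.
#' @param pattern regular expression with one capture group extracting the
#'   integer frame index from a filename; the default takes the last run
#'   of digits before the extension.
#' @param interval capture interval in minutes (default 4).
#' @param startHAS timestamp of frame index 0, hours after sowing.
#' @return A [SeriesManifest] with entries sorted by timestamp.
#' @export
loadSeries <- function(source, pattern = "(\\d+)\\.[A-Za-z]+$",
                       interval = 4, startHAS = 0) {
  if (length(source) == 1 && file.exists(source) && !dir.exists(source)) {
    tab <- utils::read.csv(source, stringsAsFactors = FALSE)
    need <- c("path", "frame_id", "timestamp_has")
    if (!all(need %in% names(tab)))
      stop("manifest must have columns: ", paste(need, collapse = ", "))
    tab <- tab[need]
  } else {
    if (!dir.exists(source)) stop("no such directory: ", source)
    files <- list.files(source, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (!length(files)) stop("no frames matched in ", source)
    m <- regmatches(basename(files), regexec(pattern, basename(files)))
    idx <- vapply(m, function(g) {
      if (length(g) < 2) NA_real_ else suppressWarnings(as.numeric(g[2]))
    }, numeric(1))
    if (anyNA(idx))
      stop("filenames not parseable with pattern '", pattern, "': ",
           paste(basename(files)[is.na(idx)], collapse = ", "))
    tab <- data.frame(path = files, frame_id = as.integer(idx),
                      timestamp_has = startHAS + idx * interval / 60,
                      stringsAsFactors = FALSE)
  }
  dup <- duplicated(tab$timestamp_has)
  if (any(dup))
    stop("duplicate timestamps for: ",
         paste(tab$path[tab$timestamp_has %in% tab$timestamp_has[dup]],
               collapse = ", "))
  tab <- tab[order(tab$timestamp_has), , drop = FALSE]
  rownames(tab) <- NULL
  new("SeriesManifest", entries = tab, interval = interval)
}

#' Write a mask or skeleton as a PNG image
#'
#' @param mask a [BinaryRootMask] or [Skeleton].
#' @param path output PNG path (foreground white, background black).
#' @return `path`, invisibly.
#' @export
writeMaskPng <- function(mask, path) {
  png::writePNG(mask@grid * 1, path)
  invisible(path)
}

#' Write skeleton pixels as a CSV of (x, y) coordinates
#'
#' @param skeleton a [Skeleton] (any [BinaryRootMask] is accepted).
#' @param path output CSV path with columns `x`, `y` (0-based).
#' @return `path`, invisibly.
#' @export
writeSkeletonCsv <- function(skeleton, path) {
  px <- .maskPixels(skeleton@grid)
  utils::write.csv(data.frame(x = px[, 1], y = px[, 2]), path,
                   row.names = FALSE)
  invisible(path)
}

# foreground pixels as an n x 2 matrix of 0-based (x, y), ordered by (y, x)
.maskPixels <- function(grid) {
  w <- which(grid, arr.ind = TRUE)
  out <- cbind(x = w[, 2] - 1L, y = w[, 1] - 1L)
  out[order(out[, 2], out[, 1]), , drop = FALSE]
}
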