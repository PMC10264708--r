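#' Reduce a binary root mask to a one-pixel skeleton
#'
#' Topology-preserving thinning: two-subiteration Zhang-Suen erosion in
#' which each subiteration's candidate set is applied sequentially under a
#' live simple-point recheck (crossing number 1, at least two foreground
#' neighbours), followed by removal of redundant corner pixels (degree-2
#' pixels whose two neighbours are mutually 8-adjacent). The sequential
#' recheck guarantees that the number of 8-connected foreground components
#' and of 4-connected background holes is preserved exactly, and that
#' endpoints are never deleted; the corner pass leaves genuine one-pixel
#' chains for graph construction. The image border is treated as
#' background, so roots touching the frame edge still end in endpoints.
#'
#' The operator is idempotent: skeletonizing a skeleton returns it
#' unchanged.
#'
#' After thinning, each skeleton endpoint is extended forward through
#' remaining mask foreground to the local extremity (straight-ahead
#' pixels preferred over 45-degree deviations, never touching the
#' skeleton elsewhere), so that root tips are recovered at every
#' orientation instead of stopping where the erosion happened to leave
#' the last simple pixel. Set `extendTips = FALSE` for the bare thinning.
#'
#' @param mask a [BinaryRootMask] (typically after [cleanMask()]; any mask
#'   is tolerated).
#' @param extendTips extend endpoints through the mask to the tip
#'   extremity (default `TRUE`).
#' @return A [Skeleton] with the same dimensions and scale.
#' @export
skeletonize <- function(mask, extendTips = TRUE) {
  stopifnot(is(mask, "BinaryRootMask"))
  g <- .thin_skeleton(mask@grid)
  if (extendTips && any(g)) g <- .extendTips(mask@grid, g)
  new("Skeleton", grid = g, scale = mask@scale)
}

# grow each endpoint forward through mask foreground; a candidate pixel
# is accepted only if its sole skeleton neighbour is the current tip, so
# the extension stays a one-pixel path and never merges with (or loops
# onto) other skeleton parts
.extendTips <- function(mask, skel) {
  H <- nrow(skel); W <- ncol(skel)
  deg <- .pixel_degree(skel)
  ep <- which(deg == 1, arr.ind = TRUE)
  if (!nrow(ep)) return(skel)
  ep <- ep[order(ep[, 1], ep[, 2]), , drop = FALSE]
  fg <- function(m, x, y) x >= 0 && y >= 0 && x < W && y < H && m[y + 1, x + 1]
  skelNb <- function(x, y) {
    nb <- 0L
    for (k in 1:8) if (fg(skel, x + .NB[k, 1], y + .NB[k, 2])) nb <- nb + 1L
    nb
  }
  for (i in seq_len(nrow(ep))) {
    ey <- ep[i, 1] - 1L; ex <- ep[i, 2] - 1L
    ux <- NA
    for (k in 1:8) if (fg(skel, ex + .NB[k, 1], ey + .NB[k, 2])) {
      ux <- ex + .NB[k, 1]; uy <- ey + .NB[k, 2]; break
    }
    if (is.na(ux)) next
    repeat {
      d <- c(sign(ex - ux), sign(ey - uy))
      cone <- if (d[1] == 0) list(d, c(-1, d[2]), c(1, d[2]))
      else if (d[2] == 0) list(d, c(d[1], -1), c(d[1], 1))
      else list(d, c(d[1], 0), c(0, d[2]))
      nxt <- NULL
      for (dd in cone) {
        cx <- ex + dd[1]; cy <- ey + dd[2]
        if (!fg(mask, cx, cy) || fg(skel, cx, cy)) next
        # the candidate may touch the skeleton only at the current tip
        ok <- TRUE
        for (k in 1:8) {
          qx <- cx + .NB[k, 1]; qy <- cy + .NB[k, 2]
          if (fg(skel, qx, qy) && !(qx == ex && qy == ey)) { ok <- FALSE; break }
        }
        if (ok) { nxt <- c(cx, cy); break }
      }
      if (is.null(nxt)) break
      skel[nxt[2] + 1L, nxt[1] + 1L] <- TRUE
      ux <- ex; uy <- ey; ex <- nxt[1]; ey <- nxt[2]
    }
  }
  skel
}
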