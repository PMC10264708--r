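# Independent oracles used across the suite. These deliberately avoid the
# package's own C++ labeling and R graph construction: labeling is done by
# vectorized label propagation, graph summaries via igraph on the pixel
# adjacency, hulls by an all-pairs half-plane test.

# connected-component count by iterative min-label propagation
oracleLabel <- function(grid, eight = TRUE) {
  H <- nrow(grid); W <- ncol(grid)
  lab <- matrix(0L, H, W)
  lab[grid] <- seq_len(sum(grid))
  shifts <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (eight) shifts <- c(shifts, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  repeat {
    new <- lab
    for (s in shifts) {
      sh <- matrix(0L, H, W)
      rs <- max(1, 1 + s[1]):min(H, H + s[1])
      cs <- max(1, 1 + s[2]):min(W, W + s[2])
      sh[rs, cs] <- lab[rs - s[1], cs - s[2]]
      sel <- grid & sh > 0 & (new == 0 | sh < new)
      new[sel] <- sh[sel]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

oracleNComp <- function(grid, eight = TRUE) {
  if (!any(grid)) return(0L)
  length(unique(oracleLabel(grid, eight)[grid]))
}

# 4-connected background holes, with a padded border so the outer
# background is a single component
oracleNHoles <- function(grid) {
  p <- matrix(FALSE, nrow(grid) + 2, ncol(grid) + 2)
  p[2:(nrow(grid) + 1), 2:(ncol(grid) + 1)] <- grid
  oracleNComp(!p, eight = FALSE) - 1L
}

# seeded random blob mask (drunken-walk strokes)
randomMask <- function(H, W, nblobs = NULL) {
  g <- matrix(FALSE, H, W)
  if (is.null(nblobs)) nblobs <- sample(2:5, 1)
  for (b in seq_len(nblobs)) {
    cx <- runif(1, 3, W - 4); cy <- runif(1, 3, H - 4)
    n <- sample(15:70, 1)
    xs <- round(cx + cumsum(rnorm(n)))
    ys <- round(cy + cumsum(rnorm(n)))
    keep <- xs >= 0 & xs < W & ys >= 0 & ys < H
    g[cbind(ys[keep] + 1, xs[keep] + 1)] <- TRUE
  }
  g
}

# dense random mask (worst-case topology: many holes and components)
randomDenseMask <- function(H, W, p = NULL) {
  if (is.null(p)) p <- runif(1, 0.25, 0.75)
  matrix(runif(H * W) < p, H, W)
}

# independent summary of a thin skeleton: adjacency pairs via brute
# force, degrees, junction clusters / pure cycles via igraph, total
# chain length and edge count in closed form
oracleGraphSummary <- function(skeleton) {
  s <- maskGrid(skeleton)
  scale <- pixelScale(skeleton)
  px <- which(s, arr.ind = TRUE)
  if (!nrow(px))
    return(list(total = 0, nEdges = 0L,
                counts = c(endpoint = 0L, junction = 0L,
                           isolated = 0L, cycle_anchor = 0L)))
  key <- paste(px[, 1], px[, 2])
  pairs <- NULL
  for (dy in -1:1) for (dx in -1:1) {
    if (dy < 0 || (dy == 0 && dx <= 0)) next
    hit <- match(paste(px[, 1] + dy, px[, 2] + dx), key)
    ok <- !is.na(hit)
    if (any(ok))
      pairs <- rbind(pairs, cbind(which(ok), hit[ok],
                                  ifelse(dx != 0 & dy != 0, sqrt(2), 1)))
  }
  npx <- nrow(px)
  deg <- if (is.null(pairs)) integer(npx) else
    tabulate(c(pairs[, 1], pairs[, 2]), nbins = npx)
  jpix <- which(deg >= 3)
  intra <- 0; njunc <- 0L; nIntraPairs <- 0L
  if (length(jpix)) {
    sel <- pairs[pairs[, 1] %in% jpix & pairs[, 2] %in% jpix, , drop = FALSE]
    gj <- igraph::make_empty_graph(n = length(jpix), directed = FALSE)
    if (nrow(sel))
      gj <- igraph::add_edges(gj, rbind(match(sel[, 1], jpix),
                                        match(sel[, 2], jpix)))
    njunc <- igraph::components(gj)$no
    intra <- if (nrow(sel)) sum(sel[, 3]) else 0
    nIntraPairs <- nrow(sel)
  }
  gAll <- igraph::make_empty_graph(n = npx, directed = FALSE)
  if (!is.null(pairs) && nrow(pairs))
    gAll <- igraph::add_edges(gAll, t(pairs[, 1:2, drop = FALSE]))
  cmp <- igraph::components(gAll)
  pure <- sum(vapply(seq_len(cmp$no), function(cc) {
    m <- cmp$membership == cc
    all(deg[m] == 2)
  }, logical(1)))
  totalPairs <- if (is.null(pairs)) 0 else sum(pairs[, 3])
  nPairs <- if (is.null(pairs)) 0L else nrow(pairs)
  list(total = (totalPairs - intra) * scale,
       nEdges = as.integer((nPairs - nIntraPairs) - (sum(deg == 2) - pure)),
       counts = c(endpoint = as.integer(sum(deg == 1)),
                  junction = as.integer(njunc),
                  isolated = as.integer(sum(deg == 0)),
                  cycle_anchor = as.integer(pure)))
}

# assemble an abstract SkeletonGraph from node and edge tables (2-pixel
# straight chains standing in for the pixel geometry)
abstractGraph <- function(nodes, edges, scale = 1) {
  chains <- lapply(seq_len(nrow(edges)), function(i) {
    u <- match(edges$u[i], nodes$id); v <- match(edges$v[i], nodes$id)
    cbind(x = c(nodes$x[u], nodes$x[v]), y = c(nodes$y[u], nodes$y[v]))
  })
  nodePixels <- lapply(seq_len(nrow(nodes)), function(i)
    cbind(x = nodes$x[i], y = nodes$y[i]))
  new("SkeletonGraph", nodes = nodes, edges = edges, chains = chains,
      nodePixels = nodePixels, scale = scale)
}

# exhaustive longest seed-anchored path via igraph simple paths
oracleLongest <- function(nodes, edges, startId) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$u), to = as.character(edges$v)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$id)))
  endp <- nodes$id[nodes$kind == "endpoint" & nodes$id != startId]
  best <- -Inf
  for (e in endp) {
    ps <- igraph::all_simple_paths(g, from = as.character(startId),
                                   to = as.character(e))
    for (p in ps) {
      ids <- as.integer(names(p))
      len <- 0
      for (k in seq_len(length(ids) - 1)) {
        sel <- (edges$u == ids[k] & edges$v == ids[k + 1]) |
               (edges$v == ids[k] & edges$u == ids[k + 1])
        len <- len + max(edges$length[sel])
      }
      if (len > best) best <- len
    }
  }
  best
}

# convex hull area by all-pairs half-plane test + shoelace
oracleHullArea <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 3) return(0)
  onHull <- logical(n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- pts[j, ] - pts[i, ]
    cr <- (pts[, 1] - pts[i, 1]) * d[2] - (pts[, 2] - pts[i, 2]) * d[1]
    if (all(cr <= 1e-9) || all(cr >= -1e-9)) onHull[c(i, j)] <- TRUE
  }
  hp <- pts[onHull, , drop = FALSE]
  ctr <- colMeans(hp)
  hp <- hp[order(atan2(hp[, 2] - ctr[2], hp[, 1] - ctr[1])), , drop = FALSE]
  j <- c(2:nrow(hp), 1)
  abs(sum(hp[, 1] * hp[j, 2] - hp[j, 1] * hp[, 2])) / 2
}

# random thin skeleton: random strokes, thinned by the package (the
# object under test for graph construction is buildGraph, not thinning)
randomSkeleton <- function(H, W) {
  skeletonize(binaryRootMask(randomDenseMask(H, W)), extendTips = FALSE)
}

# one straight/curved synthetic root on a standard canvas
singleRootCase <- function(lengthPx, headingDeg, curvature = 0, seed = 1,
                           scale = 0.1) {
  rootSystemSpec(grain = c(150, 30),
                 roots = rootSpec(heading = headingDeg, emergence = 0,
                                  growthRate = 100,
                                  maxLength = lengthPx * scale,
                                  curvature = curvature),
                 width = 320L, height = 230L, scale = scale, seed = seed)
}

measureCase <- function(spec, t = 10, exclusion = 0, config = rtConfig()) {
  mask <- rasterizeRoots(growRoots(spec, t), spec@strokeWidth, spec@width,
                         spec@height, spec@scale)
  extractTraits(mask, landmarks(spec@grain, seedExclusionRadius = exclusion),
                config)
}
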