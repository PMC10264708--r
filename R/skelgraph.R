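# 8-neighbour offsets (dx, dy), clockwise from north
.NB <- cbind(dx = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L),
             dy = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L))

#' Per-pixel neighbour degree of a skeleton
#'
#' Counts the 8-neighbour skeleton pixels of every pixel: endpoints have
#' degree 1, chain pixels 2, junction pixels 3 or more, isolated pixels 0.
#'
#' @param skeleton a [Skeleton] (any [BinaryRootMask] is accepted).
#' @return Integer matrix of the skeleton's dimensions; background pixels
#'   carry -1.
#' @export
classifyPixels <- function(skeleton) {
  .pixel_degree(skeleton@grid)
}

#' Geodesic length of a pixel chain
#'
#' The step-cost metric used by every length trait: an axial move costs 1,
#' a diagonal move sqrt(2), scaled to mm. A single-pixel chain has
#' length 0.
#'
#' @param chain n x 2 matrix of (x, y) pixels; consecutive rows must be
#'   8-neighbours.
#' @param scale mm per pixel.
#' @return Length in mm.
#' @export
chainLength <- function(chain, scale = 1) {
  chain <- as.matrix(chain)
  n <- nrow(chain)
  if (n <= 1) return(0)
  dx <- abs(diff(chain[, 1]))
  dy <- abs(diff(chain[, 2]))
  if (any(dx > 1 | dy > 1 | (dx == 0 & dy == 0)))
    stop("consecutive chain pixels must be distinct 8-neighbours")
  scale * sum(ifelse(dx & dy, sqrt(2), 1))
}

#' Convert a skeleton into a graph of endpoints, junctions and chains
#'
#' Nodes are endpoint pixels (degree 1), merged clusters of mutually
#' adjacent junction pixels (degree >= 3; the node position is the
#' integer-rounded cluster centroid), isolated pixels, and one
#' `cycle_anchor` per pure cycle (all pixels degree 2), chosen as the
#' cycle's lexicographically smallest (y, x) pixel. Edges are the maximal
#' degree-2 pixel chains between node pixels, stored inclusive of their
#' terminal node pixels, with geodesic lengths per [chainLength()];
#' parallel edges and self-loops are kept. Every skeleton pixel belongs to
#' exactly one edge chain interior or to a node.
#'
#' @param skeleton a [Skeleton].
#' @return A [SkeletonGraph].
#' @export
buildGraph <- function(skeleton) {
  g <- skeleton@grid
  H <- nrow(g); W <- ncol(g)
  deg <- .pixel_degree(g)
  px <- .maskPixels(g)

  nodeDefs <- list()  # each: list(x, y, kind, pixels [n x 2 (x,y)])
  if (nrow(px)) {
    # junction clusters: 8-connected components of degree >= 3 pixels
    jlab <- .label_cc(deg >= 3, TRUE)
    nj <- max(jlab)
    for (j in seq_len(nj)) {
      w <- which(jlab == j, arr.ind = TRUE)
      p <- cbind(x = w[, 2] - 1L, y = w[, 1] - 1L)
      p <- p[order(p[, 2], p[, 1]), , drop = FALSE]
      nodeDefs[[length(nodeDefs) + 1L]] <- list(
        x = floor(mean(p[, 1]) + 0.5), y = floor(mean(p[, 2]) + 0.5),
        kind = "junction", pixels = p)
    }
    for (kd in list(list("endpoint", 1L), list("isolated", 0L))) {
      w <- which(deg == kd[[2]], arr.ind = TRUE)
      if (nrow(w)) for (i in seq_len(nrow(w))) {
        p <- cbind(x = w[i, 2] - 1L, y = w[i, 1] - 1L)
        nodeDefs[[length(nodeDefs) + 1L]] <- list(
          x = p[1], y = p[2], kind = kd[[1]], pixels = p)
      }
    }
    # pure cycles: components containing no pixel of degree != 2
    comp <- .label_cc(g, TRUE)
    hasNode <- unique(comp[g & deg != 2])
    pure <- setdiff(unique(comp[g]), hasNode)
    for (cc in pure) {
      w <- which(comp == cc, arr.ind = TRUE)
      p <- cbind(x = w[, 2] - 1L, y = w[, 1] - 1L)
      p <- p[order(p[, 2], p[, 1]), , drop = FALSE]
      nodeDefs[[length(nodeDefs) + 1L]] <- list(
        x = p[1, 1], y = p[1, 2], kind = "cycle_anchor",
        pixels = p[1, , drop = FALSE])
    }
  }

  # deterministic ids: sort nodes by their smallest (y, x) pixel
  if (length(nodeDefs)) {
    key <- t(vapply(nodeDefs, function(n) c(n$pixels[1, 2], n$pixels[1, 1]),
                    numeric(2)))
    nodeDefs <- nodeDefs[order(key[, 1], key[, 2])]
  }
  nodeId <- matrix(0L, H, W)
  for (i in seq_along(nodeDefs)) {
    p <- nodeDefs[[i]]$pixels
    nodeId[cbind(p[, 2] + 1L, p[, 1] + 1L)] <- i
  }

  nodes <- data.frame(
    id = seq_along(nodeDefs),
    x = vapply(nodeDefs, `[[`, numeric(1), "x"),
    y = vapply(nodeDefs, `[[`, numeric(1), "y"),
    kind = vapply(nodeDefs, `[[`, character(1), "kind"),
    stringsAsFactors = FALSE)
  nodePixels <- lapply(nodeDefs, `[[`, "pixels")

  visited <- matrix(FALSE, H, W)
  eu <- integer(); ev <- integer(); chains <- list()

  fgAt <- function(x, y) x >= 0 && y >= 0 && x < W && y < H && g[y + 1, x + 1]
  degAt <- function(x, y) deg[y + 1, x + 1]
  idAt <- function(x, y) nodeId[y + 1, x + 1]

  addEdge <- function(a, b, chain) {
    eu[[length(eu) + 1L]] <<- a
    ev[[length(ev) + 1L]] <<- b
    chains[[length(chains) + 1L]] <<- chain
  }

  # scan node pixels in id order, pixels in (y, x) order within a node
  for (i in seq_along(nodeDefs)) {
    pix <- nodeDefs[[i]]$pixels
    for (r in seq_len(nrow(pix))) {
      x0 <- pix[r, 1]; y0 <- pix[r, 2]
      for (k in 1:8) {
        x1 <- x0 + .NB[k, 1]; y1 <- y0 + .NB[k, 2]
        if (!fgAt(x1, y1)) next
        id1 <- idAt(x1, y1)
        if (id1 > 0) {
          if (id1 == i) next  # same node (cluster-internal adjacency)
          # direct node-node adjacency: record once, from the (y,x)-smaller pixel
          if (y0 < y1 || (y0 == y1 && x0 < x1))
            addEdge(i, id1, cbind(x = c(x0, x1), y = c(y0, y1)))
          next
        }
        # id1 == 0: a degree-2 chain pixel
        if (visited[y1 + 1, x1 + 1]) next
        cx <- c(x0, x1); cy <- c(y0, y1)
        visited[y1 + 1, x1 + 1] <- TRUE
        px_ <- x0; py_ <- y0; cx_ <- x1; cy_ <- y1
        repeat {
          nxt <- NULL
          for (kk in 1:8) {
            xn <- cx_ + .NB[kk, 1]; yn <- cy_ + .NB[kk, 2]
            if (!fgAt(xn, yn)) next
            if (xn == px_ && yn == py_) next
            nxt <- c(xn, yn); break
          }
          if (is.null(nxt)) break  # defensive; cannot occur on degree-2 pixels
          cx <- c(cx, nxt[1]); cy <- c(cy, nxt[2])
          idn <- idAt(nxt[1], nxt[2])
          if (idn > 0) { addEdge(i, idn, cbind(x = cx, y = cy)); break }
          visited[nxt[2] + 1, nxt[1] + 1] <- TRUE
          px_ <- cx_; py_ <- cy_; cx_ <- nxt[1]; cy_ <- nxt[2]
        }
      }
    }
  }

  lens <- vapply(chains, chainLength, numeric(1), scale = skeleton@scale)
  new("SkeletonGraph",
      nodes = nodes,
      edges = data.frame(u = eu, v = ev, length = lens),
      chains = chains, nodePixels = nodePixels, scale = skeleton@scale)
}

# Anchor a graph at the grain: find the skeleton pixel nearest the grain
# (ties by (y, x)); if it is interior to a chain, split that edge there,
# promoting the pixel to an "anchor" node, so that seed-anchored paths
# start at the grain even when no endpoint or junction lies near it
# (e.g. a two-root system whose apex is a plain degree-2 bend).
# Returns list(graph, start = the node id nearest the grain).
.anchorAtGrain <- function(graph, grain) {
  n <- graph@nodes
  if (!nrow(n)) stop("no root material")
  bestD <- Inf; bestKey <- c(Inf, Inf)
  bestNode <- NA_integer_; bestEdge <- NA_integer_; bestPos <- NA_integer_
  seen <- function(d, key) d < bestD - 1e-9 ||
    (abs(d - bestD) <= 1e-9 && (key[1] < bestKey[1] ||
       (key[1] == bestKey[1] && key[2] < bestKey[2])))
  for (i in seq_len(nrow(n))) {
    p <- graph@nodePixels[[i]]
    d <- sqrt((p[, 1] - grain[1])^2 + (p[, 2] - grain[2])^2)
    j <- order(d, p[, 2], p[, 1])[1]
    if (seen(d[j], c(p[j, 2], p[j, 1]))) {
      bestD <- d[j]; bestKey <- c(p[j, 2], p[j, 1])
      bestNode <- i; bestEdge <- NA_integer_
    }
  }
  for (e in seq_along(graph@chains)) {
    ch <- graph@chains[[e]]
    if (nrow(ch) <= 2) next
    idx <- 2:(nrow(ch) - 1)
    d <- sqrt((ch[idx, 1] - grain[1])^2 + (ch[idx, 2] - grain[2])^2)
    j <- order(d, ch[idx, 2], ch[idx, 1])[1]
    if (seen(d[j], c(ch[idx[j], 2], ch[idx[j], 1]))) {
      bestD <- d[j]; bestKey <- c(ch[idx[j], 2], ch[idx[j], 1])
      bestNode <- NA_integer_; bestEdge <- e; bestPos <- idx[j]
    }
  }
  if (is.na(bestEdge)) return(list(graph = graph, start = n$id[bestNode]))
  ch <- graph@chains[[bestEdge]]
  newId <- nrow(n) + 1L
  ch1 <- ch[seq_len(bestPos), , drop = FALSE]
  ch2 <- ch[bestPos:nrow(ch), , drop = FALSE]
  e <- graph@edges
  nodes <- rbind(n, data.frame(id = newId, x = ch[bestPos, 1],
                               y = ch[bestPos, 2], kind = "anchor"))
  edges <- rbind(e[-bestEdge, , drop = FALSE],
                 data.frame(u = c(e$u[bestEdge], newId),
                            v = c(newId, e$v[bestEdge]),
                            length = c(chainLength(ch1, graph@scale),
                                       chainLength(ch2, graph@scale))))
  rownames(nodes) <- rownames(edges) <- NULL
  g2 <- new("SkeletonGraph", nodes = nodes, edges = edges,
            chains = c(graph@chains[-bestEdge], list(ch1, ch2)),
            nodePixels = c(graph@nodePixels,
                           list(ch[bestPos, , drop = FALSE])),
            scale = graph@scale)
  list(graph = g2, start = newId)
}

# connected-component label per node id (union over edges)
.graphComponents <- function(graph) {
  n <- nrow(graph@nodes)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  e <- graph@edges
  for (i in seq_len(nrow(e))) {
    a <- find(e$u[i]); b <- find(e$v[i])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

# rebuild the skeleton pixel grid from a graph's chains and node pixels
.graphGrid <- function(graph) {
  allpx <- do.call(rbind, c(graph@chains, graph@nodePixels))
  if (is.null(allpx) || !nrow(allpx))
    return(matrix(FALSE, 1, 1))
  H <- max(allpx[, 2]) + 1L; W <- max(allpx[, 1]) + 1L
  g <- matrix(FALSE, H, W)
  g[cbind(allpx[, 2] + 1L, allpx[, 1] + 1L)] <- TRUE
  g
}

#' Remove short terminal spurs from a skeleton graph
#'
#' Iteratively deletes edges shorter than `minLenMm` that end in an
#' endpoint node (thinning barbs), then rebuilds the graph from the
#' surviving pixels so that a junction reduced to degree 2 dissolves and
#' its two chains merge. Short self-loops at junction nodes — 1-2 px
#' cycles that 8-connected thinning leaves where strokes cross, e.g. at
#' the grain — are collapsed the same way. An edge that is its
#' component's only edge is never removed, so no root component is ever
#' emptied. One edge per component is removed per pass (shortest first)
#' until none qualifies.
#'
#' @param graph a [SkeletonGraph].
#' @param minLenMm spur length threshold in mm; 0 disables pruning.
#' @return The pruned [SkeletonGraph].
#' @export
pruneSpurs <- function(graph, minLenMm) {
  if (minLenMm <= 0) return(graph)
  repeat {
    e <- graph@edges; n <- graph@nodes
    if (!nrow(e)) return(graph)
    endp <- n$id[n$kind == "endpoint"]
    junc <- n$id[n$kind == "junction"]
    cand <- which(((e$u %in% endp | e$v %in% endp) |
                     (e$u == e$v & e$u %in% junc)) & e$length < minLenMm)
    if (!length(cand)) return(graph)
    comp <- .graphComponents(graph)
    ecomp <- comp[e$u]
    nPerComp <- table(ecomp)
    cand <- cand[nPerComp[as.character(ecomp[cand])] > 1]
    if (!length(cand)) return(graph)
    # shortest candidate within each component
    pick <- vapply(split(cand, ecomp[cand]),
                   function(ix) ix[which.min(e$length[ix])], integer(1))
    grid <- .graphGrid(graph)
    for (i in pick) {
      ch <- graph@chains[[i]]
      if (nrow(ch) > 2) {
        interior <- ch[-c(1, nrow(ch)), , drop = FALSE]
        grid[cbind(interior[, 2] + 1L, interior[, 1] + 1L)] <- FALSE
      }
      for (side in c(e$u[i], e$v[i])) {
        if (n$kind[side] == "endpoint") {
          p <- graph@nodePixels[[side]]
          grid[cbind(p[, 2] + 1L, p[, 1] + 1L)] <- FALSE
        }
      }
    }
    graph <- buildGraph(new("Skeleton", grid = grid, scale = graph@scale))
  }
}

#' Export a skeleton graph as JSON
#'
#' Writes nodes (id, x, y, kind), and edges (u, v, length_mm, chain as a
#' list of (x, y) pairs) to a JSON file.
#'
#' @param graph a [SkeletonGraph].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGraphJson <- function(graph, path) {
  out <- list(
    scale_mm_per_px = graph@scale,
    nodes = graph@nodes,
    edges = lapply(seq_len(nrow(graph@edges)), function(i) {
      list(u = graph@edges$u[i], v = graph@edges$v[i],
           length_mm = graph@edges$length[i],
           chain = unname(apply(graph@chains[[i]], 1, function(p)
             c(p[[1]], p[[2]]), simplify = FALSE)))
    }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
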