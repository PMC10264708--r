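test_that("rootArea counts foreground times squared scale", {
  expect_equal(rootArea(binaryRootMask(matrix(FALSE, 4, 4))), 0)
  g <- matrix(FALSE, 10, 10); g[sample(100, 37)] <- TRUE
  expect_equal(rootArea(binaryRootMask(g)), 37)
  expect_equal(rootArea(binaryRootMask(g, scale = 0.2)), 37 * 0.04)
})

test_that("totalRootLength sums edge lengths (empty graph gives 0)", {
  g <- matrix(FALSE, 4, 4)
  expect_equal(totalRootLength(buildGraph(new("Skeleton", grid = g,
                                              scale = 1))), 0)
  ring <- matrix(FALSE, 7, 7)
  ring[cbind(c(4, 3, 2, 3, 4, 5, 6, 5), c(2, 3, 4, 5, 6, 5, 4, 3))] <- TRUE
  expect_equal(totalRootLength(buildGraph(new("Skeleton", grid = ring,
                                              scale = 1))), 8 * sqrt(2))
})

test_that("longestRoot returns the single edge of a single-edge graph", {
  g <- matrix(FALSE, 3, 10); g[2, 2:9] <- TRUE
  gr <- buildGraph(new("Skeleton", grid = g, scale = 1))
  lr <- longestRoot(gr, landmarks(c(1, 1), seedExclusionRadius = 0))
  expect_equal(lr$length, 7)
  expect_equal(nrow(lr$pixels), 8)
  expect_error(longestRoot(buildGraph(new("Skeleton",
                                          grid = matrix(FALSE, 3, 3),
                                          scale = 1)),
                           landmarks(c(0, 0))), "no root material")
})

test_that("longestRoot picks the longer branch of a Y from the grain", {
  g <- matrix(FALSE, 20, 20)
  g[2:11, 10] <- TRUE; g[12:17, 9] <- TRUE; g[12:15, 11] <- TRUE
  gr <- buildGraph(new("Skeleton", grid = g, scale = 1))
  lm <- landmarks(c(9, 1), seedExclusionRadius = 0)  # grain at stem top
  lr <- longestRoot(gr, lm)
  e <- graphEdges(gr)
  expect_equal(lr$length, max(e$length[e$length < 9]) + 9)
  expect_equal(graphNodes(gr)$kind[lr$terminal], "endpoint")
  # terminal is the tip of the 6-px branch (x = 8)
  expect_equal(graphNodes(gr)$x[lr$terminal], 8)
})

test_that("longestRoot equals exhaustive enumeration on trees and cycles", {
  set.seed(17)
  for (rep in 1:30) {
    n <- sample(4:9, 1)
    nodes <- data.frame(id = 1:n,
                        x = sample(0:60, n), y = sample(0:60, n),
                        kind = "junction", stringsAsFactors = FALSE)
    parent <- c(NA, vapply(2:n, function(i) sample(i - 1, 1), numeric(1)))
    edges <- data.frame(u = parent[-1], v = 2:n,
                        length = round(runif(n - 1, 0.5, 10), 3))
    if (rep %% 2 == 0 && n >= 5) {
      # add one chord to create a single cycle
      pick <- sample(n, 2)
      if (!any((edges$u == pick[1] & edges$v == pick[2]) |
               (edges$u == pick[2] & edges$v == pick[1])))
        edges <- rbind(edges, data.frame(u = pick[1], v = pick[2],
                                         length = round(runif(1, 0.5, 10), 3)))
    }
    deg <- tabulate(c(edges$u, edges$v), nbins = n)
    nodes$kind[deg == 1] <- "endpoint"
    if (all(deg != 1)) next
    gr <- abstractGraph(nodes, edges)
    start <- which.max(deg)  # anchor the grain at a well-connected node
    lm <- landmarks(c(nodes$x[start], nodes$y[start]),
                    seedExclusionRadius = 0)
    lr <- longestRoot(gr, lm)
    expect_equal(lr$length, oracleLongest(nodes, edges, start),
                 tolerance = 1e-9)
    expect_equal(anyDuplicated(lr$nodes), 0)  # simple path
  }
})

test_that("primaryRootAngle reads the principal axis in (0, 180]", {
  vert <- cbind(x = rep(4, 10), y = 0:9)
  expect_equal(primaryRootAngle(vert), 90)
  diag45 <- cbind(x = 0:9, y = 0:9)
  expect_equal(primaryRootAngle(diag45), 45)
  horiz <- cbind(x = 0:9, y = rep(2, 10))
  expect_equal(primaryRootAngle(horiz), 180)
  expect_error(primaryRootAngle(cbind(x = c(2, 2), y = c(3, 3))),
               "distinct")
  # jittered diagonal stays within 1 degree of the clean fit
  set.seed(5)
  jit <- cbind(x = 0:40 + runif(41, -0.5, 0.5),
               y = 0:40 + runif(41, -0.5, 0.5))
  expect_lt(abs(primaryRootAngle(jit) - 45), 1)
  # orthogonal-regression oracle on the same points (total least squares)
  pc <- prcomp(jit)
  oracle <- (atan2(pc$rotation[2, 1], pc$rotation[1, 1]) * 180 / pi) %% 180
  expect_equal(primaryRootAngle(jit), oracle, tolerance = 1e-6)
})

test_that("convexHullArea matches pixel-center geometry and an oracle", {
  g <- matrix(FALSE, 5, 5); g[3, 3] <- TRUE
  expect_equal(convexHullArea(binaryRootMask(g)), 0)
  rect <- matrix(FALSE, 15, 25); rect[2:12, 2:22] <- TRUE  # 11 x 21 filled
  expect_equal(convexHullArea(binaryRootMask(rect)), 200)
  expect_equal(convexHullArea(binaryRootMask(rect, scale = 0.5)), 50)
  expect_error(convexHullArea(binaryRootMask(matrix(FALSE, 3, 3))),
               "empty")
  set.seed(9)
  for (i in 1:10) {
    g <- matrix(FALSE, 20, 20); g[sample(400, 25)] <- TRUE
    px <- which(g, arr.ind = TRUE)
    expect_equal(convexHullArea(binaryRootMask(g)),
                 oracleHullArea(cbind(px[, 2] - 1, px[, 1] - 1)),
                 tolerance = 1e-9)
  }
})

test_that("boundingBoxWidth is the inclusive pixel extent", {
  g <- matrix(FALSE, 5, 30); g[3, 3] <- TRUE
  expect_equal(boundingBoxWidth(binaryRootMask(g)), 1)
  g[2, 6:21] <- TRUE  # columns 5..20
  expect_equal(boundingBoxWidth(binaryRootMask(g)), 21 - 3 + 1)
  vert <- matrix(FALSE, 30, 5); vert[3:28, 3] <- TRUE
  expect_equal(boundingBoxWidth(binaryRootMask(vert)), 1)
  expect_equal(boundingBoxWidth(binaryRootMask(vert, scale = 0.1)), 0.1)
  expect_error(boundingBoxWidth(binaryRootMask(matrix(FALSE, 2, 2))),
               "empty")
})

test_that("seminalTips honours manual overrides and partitions branches", {
  tips <- cbind(c(10, 30), c(40, 40))
  g <- matrix(FALSE, 20, 20); g[2:11, 10] <- TRUE
  gr <- buildGraph(new("Skeleton", grid = g, scale = 1))
  got <- seminalTips(gr, landmarks(c(9, 1), manualTips = tips), k = 2)
  expect_identical(got, tips)
  # symmetric two-branch system: the two branch tips
  v <- matrix(FALSE, 22, 30)
  v[cbind(2:11, 15:24)] <- TRUE   # down-right diagonal
  v[cbind(2:11, 15:6)] <- TRUE    # down-left diagonal
  grv <- buildGraph(new("Skeleton", grid = v, scale = 1))
  lmv <- landmarks(c(14, 1), seedExclusionRadius = 0)
  tv <- seminalTips(grv, lmv, k = 2)
  expect_setequal(tv[, 1], c(5, 23))
  expect_equal(tv[, 2], c(10, 10))
  expect_error(seminalTips(grv, lmv, k = 5), "fewer than 5 endpoints")
})

test_that("rga is the protractor angle of the farthest tip", {
  lm <- landmarks(c(100, 50), seedExclusionRadius = 0)
  expect_equal(rga(lm, cbind(130, 100)), atan(50 / 30) * 180 / pi)
  expect_equal(rga(lm, cbind(100, 120)), 90)
  # the 60-px tip defines the angle, not the 40-px one
  tips <- rbind(c(100 + 40, 50), c(100, 50 + 60))
  expect_equal(rga(lm, tips), 90)
  expect_error(rga(lm, cbind(100, 50)), "coincides")
})

test_that("srga is the vertex angle at the grain", {
  lm <- landmarks(c(0, 0), seedExclusionRadius = 0)
  expect_equal(srga(lm, c(3, 4), c(6, 8)), 0)
  expect_equal(srga(lm, c(0, 5), c(0, -5)), 180)
  a <- 54.65 * pi / 180
  t1 <- c(-sin(a), cos(a)) * 50
  t2 <- c(sin(a), cos(a)) * 80
  expect_equal(srga(lm, t1, t2), 109.3, tolerance = 1e-9)
  expect_error(srga(lm, c(0, 0), c(1, 1)), "coincides")
})

test_that("extractTraits yields an all-zero record for empty frames", {
  rec <- extractTraits(binaryRootMask(matrix(FALSE, 30, 30)),
                       landmarks(c(15, 15)), frameId = 3L,
                       timestampHAS = 12.5)
  expect_equal(rec$frame_id, 3L)
  expect_equal(rec$timestamp_has, 12.5)
  expect_equal(rec$root_area, 0)
  expect_equal(rec$total_root_length, 0)
  expect_true(is.na(rec$primary_root_angle))
  expect_true(is.na(rec$srga))
  expect_named(rec, traitColumns())
})

test_that("extractTraits recovers a single straight root's traits", {
  spec <- singleRootCase(80, -20, seed = 4)
  gt <- groundTruth(spec, 10)
  rec <- measureCase(spec)
  expect_lt(abs(rec$total_root_length - gt$total_length_digital_mm - 0.2) /
              gt$total_length_digital_mm, 0.05)
  expect_lte(rec$longest_root_length, rec$total_root_length)
  expect_lt(abs(rec$longest_root_length - gt$total_length_digital_mm - 0.2) /
              gt$total_length_digital_mm, 0.05)
  # heading -20 deg from vertical leans toward -x: 110 deg to horizontal
  expect_lt(abs(rec$primary_root_angle - 110), 2)
  expect_lt(abs(rec$bounding_box_width - gt$bbox_width_inflated_mm), 0.1)
})

test_that("longest root never exceeds total length on multi-root systems", {
  for (s in 1:3) {
    spec <- rootSystemSpec(grain = c(150, 20), roots = rbind(
      rootSpec(heading = 0, emergence = 0, growthRate = 10, maxLength = 12),
      rootSpec(heading = -40, emergence = 1, growthRate = 10, maxLength = 8),
      rootSpec(heading = 35, emergence = 2, growthRate = 10, maxLength = 9)),
      width = 320L, height = 230L, scale = 0.1, seed = s)
    rec <- measureCase(spec, t = 5)
    expect_lte(rec$longest_root_length, rec$total_root_length + 1e-9)
    expect_lte(rec$convex_hull_area,
               rec$bounding_box_width *
                 (diff(range(which(rowSums(maskGrid(rasterizeRoots(
                   growRoots(spec, 5), 3, 320L, 230L, 0.1))) > 0))) + 1) * 0.1)
  }
})

test_that("traits are invariant/equivariant under 90-degree rotation", {
  spec <- singleRootCase(70, 25, seed = 2)
  mask <- rasterizeRoots(growRoots(spec, 10), 3, spec@width, spec@height,
                         spec@scale)
  rot <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  mask90 <- binaryRootMask(rot(maskGrid(mask)), pixelScale(mask))
  lm <- landmarks(spec@grain, seedExclusionRadius = 0)
  g90 <- c(nrow(maskGrid(mask)) - 1 - spec@grain[2], spec@grain[1])
  lm90 <- landmarks(g90, seedExclusionRadius = 0)
  a <- extractTraits(mask, lm); b <- extractTraits(mask90, lm90)
  expect_equal(b$root_area, a$root_area)
  expect_equal(b$total_root_length, a$total_root_length, tolerance = 0.02)
  expect_equal(b$convex_hull_area, a$convex_hull_area, tolerance = 0.02)
  expect_equal(b$primary_root_angle %% 180,
               (a$primary_root_angle + 90) %% 180, tolerance = 1)
})

test_that("lengths scale linearly and areas quadratically with the scale", {
  spec <- singleRootCase(60, -35, seed = 3)
  mask1 <- rasterizeRoots(growRoots(spec, 10), 3, spec@width, spec@height,
                          scale = 0.1)
  mask2 <- binaryRootMask(maskGrid(mask1), scale = 0.3)
  lm <- landmarks(spec@grain, seedExclusionRadius = 0)
  a <- extractTraits(mask1, lm); b <- extractTraits(mask2, lm)
  expect_equal(b$total_root_length, 3 * a$total_root_length)
  expect_equal(b$root_area, 9 * a$root_area)
  expect_equal(b$convex_hull_area, 9 * a$convex_hull_area)
  expect_equal(b$bounding_box_width, 3 * a$bounding_box_width)
  expect_equal(b$primary_root_angle, a$primary_root_angle)
})

test_that("SRGA tracks the generator's tip vectors on two-root systems", {
  for (s in 1:3) for (nm in c("GP-like", "BCC93-like")) {
    spec <- genotypePreset(nm, seed = s, wobbleSd = 0)
    gt <- groundTruth(spec, 168)
    rec <- measureCase(spec, t = 168)
    expect_lt(abs(rec$srga - gt$srga_deg), 2)
    expect_lt(abs(rec$srga - if (nm == "GP-like") 109.3 else 62.7), 2)
  }
})
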