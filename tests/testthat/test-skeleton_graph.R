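test_that("thinning reduces bars, blobs and crosses to their centerlines", {
  # 3 px wide, 100 px long bar -> one clean path (oracle-frozen length 96:
  # thinning retracts each blunt end by about half the bar width)
  bar <- matrix(FALSE, 20, 120); bar[9:11, 11:110] <- TRUE
  sk <- skeletonize(bar)
  g <- build_graph(sk, NULL, resolution = 1)
  expect_length(g$segments, 1)
  expect_equal(sum(g$nodes$kind == "tip"), 2)
  expect_equal(total_length_um(g), 96)

  # filled disk: no elongated structure, skeleton collapses to a point
  d <- disk_mask(101, 101, circle_px(c(51, 51), 30))
  expect_lte(sum(skeletonize(d)), 5)

  # plus-shaped cross of two 3 px bars: one junction, four tips
  p <- matrix(FALSE, 121, 121)
  p[60:62, 11:110] <- TRUE; p[11:110, 60:62] <- TRUE
  gp <- build_graph(skeletonize(p), NULL, resolution = 1)
  expect_equal(sum(gp$nodes$kind == "junction"), 1)
  expect_equal(sum(gp$nodes$kind == "tip"), 4)
  expect_length(gp$segments, 4)

  # empty in, empty out
  expect_equal(sum(skeletonize(matrix(FALSE, 10, 10))), 0)
})

test_that("graph building classifies nodes and segments on a Y", {
  m <- y_skeleton()
  bead <- circle_px(c(2, 60), 6)     # stem end (10, 60) is 2 px from circle
  g <- build_graph(m, bead, resolution = 1, base_contact_px = 3)
  expect_equal(sum(g$nodes$kind == "junction"), 1)
  expect_equal(sum(g$nodes$kind == "base"), 1)
  expect_equal(sum(g$nodes$kind == "tip"), 2)
  expect_length(g$segments, 3)
  cls <- lapply(g$segments, `[[`, "classes")
  expect_equal(sum(vapply(cls, function(x) setequal(x, c("bifurcating", "primary")),
                          logical(1))), 1)
  expect_equal(sum(vapply(cls, function(x) identical(x, "tip"), logical(1))), 2)

  # single path bead -> tip is both primary and tip
  straight <- matrix(FALSE, 40, 120); straight[20, 10:110] <- TRUE
  g1 <- build_graph(straight, circle_px(c(8, 20), 3), resolution = 1,
                    base_contact_px = 3)
  expect_length(g1$segments, 1)
  expect_setequal(g1$segments[[1]]$classes, c("primary", "tip"))

  # two disjoint Ys: counts add
  m2 <- matrix(FALSE, 260, 120)
  m2[1:120, ] <- y_skeleton()
  m2[141:260, ] <- y_skeleton()
  g2 <- suppressWarnings(build_graph(m2, NULL, resolution = 1))
  expect_equal(sum(g2$nodes$kind == "junction"), 2)
  expect_equal(sum(g2$nodes$kind == "tip"), 6)   # no bead: bases become tips
  expect_length(g2$segments, 6)

  # no skeleton pixel near the bead -> warning, graph still returned
  expect_warning(build_graph(y_skeleton(), circle_px(c(200, 200), 10),
                             resolution = 1),
                 "no base nodes")
})

test_that("segment lengths use the geodesic pixel metric", {
  m <- matrix(FALSE, 60, 60)
  for (i in 0:40) m[10 + i, 10 + i] <- TRUE   # pure diagonal
  g <- suppressWarnings(build_graph(m, NULL, resolution = 2))
  expect_equal(total_length_um(g), 40 * sqrt(2) * 2, tolerance = 1e-12)
})

test_that("pruning removes short spurs, keeps primaries, reaches a fixpoint", {
  mk_graph <- function(spur_len, spur_primary = FALSE) {
    nodes <- data.frame(
      id = 1:4,
      x = c(0, 100, 200, 100), y = c(0, 0, 0, spur_len),
      kind = c(if (spur_primary) "tip" else "base", "junction", "tip",
               if (spur_primary) "base" else "tip"),
      stringsAsFactors = FALSE)
    segs <- list(
      list(polyline = cbind(seq(0, 100), 0), nodes = c(1L, 2L)),
      list(polyline = cbind(seq(100, 200), 0), nodes = c(2L, 3L)),
      list(polyline = cbind(100, seq(0, spur_len)), nodes = c(2L, 4L)))
    skeleton_graph(nodes, segs, bead = circle_px(c(-5, 0), 4),
                   resolution_um_per_px = 1)
  }

  # 40 px spur, not primary: removed; the junction dissolves and the two
  # long segments merge with their lengths summed exactly
  g <- mk_graph(40)
  pg <- prune(g, min_len_px = 50)
  expect_length(pg$segments, 1)
  expect_equal(total_length_um(pg), 200)
  expect_false("junction" %in% pg$nodes$kind)

  # same spur flagged primary: retained
  gp <- prune(mk_graph(40, spur_primary = TRUE), min_len_px = 50)
  expect_length(gp$segments, 3)

  # 60 px spur: retained; prune is idempotent
  g60 <- prune(mk_graph(60), min_len_px = 50)
  expect_length(g60$segments, 3)
  expect_identical(prune(g60, min_len_px = 50)$segments, g60$segments)
  expect_identical(prune(pg, min_len_px = 50)$segments, pg$segments)
})

test_that("cascaded pruning re-tips junctions", {
  # junction with two short tip daughters: both pruned, the junction becomes
  # a tip and the stem becomes a (long) tip segment
  nodes <- data.frame(id = 1:4, x = c(0, 100, 130, 130),
                      y = c(0, 0, 30, -30),
                      kind = c("base", "junction", "tip", "tip"),
                      stringsAsFactors = FALSE)
  segs <- list(
    list(polyline = cbind(seq(0, 100), 0), nodes = c(1L, 2L)),
    list(polyline = cbind(seq(100, 130), seq(0, 30)), nodes = c(2L, 3L)),
    list(polyline = cbind(seq(100, 130), seq(0, -30)), nodes = c(2L, 4L)))
  g <- skeleton_graph(nodes, segs, resolution_um_per_px = 1)
  pg <- prune(g, min_len_px = 50)
  expect_length(pg$segments, 1)
  expect_setequal(pg$segments[[1]]$classes, c("primary", "tip"))
})

test_that("phantom trees satisfy Euler consistency after pruning", {
  sp <- roundtrip_spec(3)
  net <- generate_network(sp)
  img <- render_image(net, day = 12)
  res <- process_image(img, run_config())
  n_tip <- res$record$N_tip
  n_pb <- res$record$N_pb
  expect_equal(length(res$graph$segments), 2 * n_tip - n_pb)
})
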