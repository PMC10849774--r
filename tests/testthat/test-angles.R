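test_that("sector angles and the smallest-of-three selection are exact", {
  m <- measure_node(star_graph(c(0, 120, 240)), 1L)
  expect_equal(sort(m$raw_angles_deg), c(120, 120, 120), tolerance = 1e-9)
  expect_equal(m$selected_angle_deg, 120, tolerance = 1e-9)

  m2 <- measure_node(star_graph(c(0, 60, 180)), 1L)
  expect_equal(sort(m2$raw_angles_deg), c(60, 120, 180), tolerance = 1e-9)
  expect_equal(m2$selected_angle_deg, 60, tolerance = 1e-9)

  # raw angles always sum to 360
  expect_equal(sum(m2$raw_angles_deg), 360, tolerance = 1e-9)
})

test_that("nodes of degree other than three are skipped with a reason", {
  g4 <- star_graph(c(0, 90, 180, 270))
  s <- measure_node(g4, 1L)
  expect_s3_class(s, "angle_skip")
  expect_match(s$reason, "degree 4")

  # arm shorter than 5 px -> indeterminate
  gs <- star_graph(c(0, 120, 240), arm_len = 3)
  ms <- measure_node(gs, 1L)
  expect_equal(ms$classification, "indeterminate")
  expect_true(is.na(ms$selected_angle_deg))
})

test_that("the outward-bisector filter separates bifurcations from anastomoses", {
  bead <- circle_px(c(0, 0), 10)
  # node east of the bead, selected angle opening further east -> bifurcation
  g_out <- star_graph(c(-30, 30, 180), node = c(100, 0), bead = bead)
  expect_equal(measure_node(g_out, 1L)$classification, "bifurcation")

  # mirrored: selected angle opening back toward the bead -> anastomosis
  g_in <- star_graph(c(150, 210, 0), node = c(100, 0), bead = bead)
  expect_equal(measure_node(g_in, 1L)$classification, "anastomosis")

  # bisector exactly perpendicular to the radial vector: 90 deg inclusive
  g_perp <- star_graph(c(60, 120, 270), node = c(100, 0), bead = bead)
  mp <- measure_node(g_perp, 1L)
  expect_equal(mp$bisector_angle_to_radial_deg, 90, tolerance = 1e-9)
  expect_equal(mp$classification, "bifurcation")

  # zero-length bisector is indeterminate
  fake <- structure(list(selected_angle_deg = 90, bisector = c(0, 0),
                         node_xy = c(50, 0), classification = "unclassified"),
                    class = "angle_measurement")
  expect_equal(classify_bifurcation(fake, c(0, 0))$classification,
               "indeterminate")
})

test_that("selection and classification are rotation invariant", {
  set.seed(42)
  bead <- circle_px(c(0, 0), 10)
  for (i in 1:20) {
    bearings <- sort(runif(3, 0, 360))
    base <- measure_node(star_graph(bearings, node = c(150, 0), bead = bead), 1L)
    theta <- runif(1, 0, 360)
    node2 <- 150 * c(cos(theta * pi / 180), sin(theta * pi / 180))
    rot <- measure_node(star_graph(bearings + theta, node = node2, bead = bead), 1L)
    expect_equal(rot$selected_angle_deg, base$selected_angle_deg,
                 tolerance = 1e-6)
    expect_equal(rot$classification, base$classification)
    # pigeonhole: smallest of three sector angles never exceeds 120
    expect_lte(base$selected_angle_deg, 120 + 1e-9)
  }
})

test_that("angle pooling reports mean and SEM over classified bifurcations", {
  # two junctions with selected angles 50 and 70, both opening outward
  bead <- circle_px(c(0, 0), 10)
  nodes <- data.frame(id = 1:8,
                      x = c(300, 0, 400, 390, 250, -30, 30, 0),
                      y = c(0, 300, 90, -90, 0, 400, 400, 200),
                      kind = c("junction", "junction", rep("tip", 6)),
                      stringsAsFactors = FALSE)
  arm <- function(from, bearing, len = 100) {
    a <- bearing * pi / 180
    tt <- seq(0, len, by = 1)
    cbind(from[1] + tt * cos(a), from[2] + tt * sin(a))
  }
  segs <- list(
    list(polyline = arm(c(300, 0), 25), nodes = c(1L, 3L)),
    list(polyline = arm(c(300, 0), -25), nodes = c(1L, 4L)),
    list(polyline = arm(c(300, 0), 180), nodes = c(1L, 5L)),
    list(polyline = arm(c(0, 300), 90 + 35), nodes = c(2L, 6L)),
    list(polyline = arm(c(0, 300), 90 - 35), nodes = c(2L, 7L)),
    list(polyline = arm(c(0, 300), 270), nodes = c(2L, 8L)))
  g <- skeleton_graph(nodes, segs, bead = bead, resolution_um_per_px = 1)
  ad <- angle_distribution(g)
  expect_equal(sort(ad$angles_deg), c(50, 70), tolerance = 1e-9)
  expect_equal(ad$mean_deg, 60, tolerance = 1e-9)
  expect_equal(ad$sem_deg, 10, tolerance = 1e-9)
  expect_equal(ad$n, 2L)

  # degenerate summaries
  one <- angle_distribution(star_graph(c(-25, 25, 180), node = c(100, 0),
                                       bead = bead))
  expect_equal(one$n, 1L)
  expect_equal(one$sem_deg, 0)
})

test_that("the Laplacian reference angle is 2pi/5 in degrees", {
  expect_equal(laplacian_reference_angle(), 72)
  expect_equal(laplacian_reference_angle(), (2 / 5) * 180)
  expect_gt(laplacian_reference_angle(), 0)
  expect_lt(laplacian_reference_angle(), 180)
})

test_that("rendered bifurcations measure within 3 degrees of truth", {
  for (phi in c(50, 70)) {
    img <- v_fixture_image(width_um = 10, phi_deg = phi)
    res <- process_image(img, run_config())
    ad <- angle_distribution(res$graph)
    expect_equal(ad$n, 1L)
    expect_lt(abs(ad$angles_deg - phi), 3)
  }
})
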