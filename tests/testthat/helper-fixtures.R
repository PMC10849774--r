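# Shared fixtures: all built in code, nothing stored on disk.

# Calibrated image of a bead plus one primary that bifurcates into two
# straight daughters at +-phi/2 about the horizontal.
v_fixture_image <- function(width_um = 10, phi_deg = 70, size = 900L,
                            noise = 0, seed = 7, res = 1.25,
                            bead_radius_px = 106) {
  ctr <- c((size + 1) / 2, (size + 1) / 2)
  p0 <- ctr + c(bead_radius_px, 0)
  apex <- p0 + c(120, 0)
  t1 <- seq(0, 120, by = 0.5)
  prim <- cbind(p0[1] + t1, p0[2])
  t2 <- seq(0, 150, by = 0.5)
  a <- phi_deg / 2 * pi / 180
  d1 <- cbind(apex[1] + t2 * cos(a), apex[2] + t2 * sin(a))
  d2 <- cbind(apex[1] + t2 * cos(-a), apex[2] + t2 * sin(-a))
  canvas <- matrix(2000, size, size)
  canvas <- sproutgraph:::stamp_disks_cpp(canvas, ctr[1], ctr[2],
                                          bead_radius_px, 3200)
  hw <- width_um / res / 2
  for (p in list(prim, d1, d2))
    canvas <- sproutgraph:::stamp_disks_cpp(canvas, p[, 1], p[, 2], hw, 3200)
  if (noise > 0) {
    set.seed(seed)
    canvas <- canvas + matrix(rnorm(size * size, 0, noise), size, size)
  }
  calibrated_image(pmin(pmax(canvas, 0), 65535), res, bead_id = 1, day = 1)
}

# Synthetic skeleton graph: one junction at `node` with three straight arms
# at the given bearings (degrees, 0 = +x, counter-clockwise in x/y terms).
star_graph <- function(bearings_deg, arm_len = 100, node = c(200, 200),
                       bead = NULL, res = 1.25) {
  nodes <- data.frame(id = 1L, x = node[1], y = node[2], kind = "junction",
                      stringsAsFactors = FALSE)
  segs <- list()
  for (i in seq_along(bearings_deg)) {
    a <- bearings_deg[i] * pi / 180
    tt <- seq(0, arm_len, by = 1)
    poly <- cbind(node[1] + tt * cos(a), node[2] + tt * sin(a))
    nodes <- rbind(nodes, data.frame(id = i + 1L, x = poly[nrow(poly), 1],
                                     y = poly[nrow(poly), 2], kind = "tip",
                                     stringsAsFactors = FALSE))
    segs[[i]] <- list(polyline = poly, nodes = c(1L, i + 1L))
  }
  skeleton_graph(nodes, segs, bead = bead, resolution_um_per_px = res)
}

# Pixel-level Y skeleton in a logical matrix: horizontal stem from
# (x=10, y=60) to (60, 60), then two diagonal arms to (100, 20)/(100, 100).
y_skeleton <- function() {
  m <- matrix(FALSE, 120, 120)
  m[60, 10:60] <- TRUE
  for (i in 1:40) {
    m[60 - i, 60 + i] <- TRUE
    m[60 + i, 60 + i] <- TRUE
  }
  m
}

# Well-separated-branch phantom used by the round-trip acceptance tests:
# inter-branch refractory > 3x sprout width, topology frozen at the
# inflection day, sub-pruning-scale stubs retracted (see methods vignette).
roundtrip_spec <- function(seed) {
  phantom_spec(n_primary = 5, mean_segment_length_um = 150,
               branch_angle_mean_deg = 70, branch_angle_sd_deg = 10,
               sprout_width_um = 10,
               logistic_params = list(Y_max = 3500, k = 1.2, t1 = 6),
               min_branch_arclength_um = 35, branch_until_day = 6,
               retract_stubs_um = 80, rng_seed = seed)
}
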