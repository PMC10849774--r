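## Bifurcation angles at degree-3 junction nodes: fixed-arclength arm
## points, smallest-of-three selection, and an outward-bisector filter that
## separates bifurcations from anastomoses.

.arm_point <- function(poly, from_start, arm_px) {
  # point at exact arclength arm_px along the polyline, measured from the
  # first (from_start = TRUE) or last row; clamps to the far end
  if (!from_start) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  if (nrow(poly) < 2) return(list(point = poly[1, ], short = TRUE, len = 0))
  d <- sqrt(rowSums(diff(poly)^2))
  cum <- c(0, cumsum(d))
  total <- cum[length(cum)]
  if (total <= arm_px) return(list(point = poly[nrow(poly), ], short = TRUE,
                                   len = total))
  i <- findInterval(arm_px, cum)           # cum[i] <= arm < cum[i+1]
  f <- (arm_px - cum[i]) / d[i]
  list(point = poly[i, ] + f * (poly[i + 1, ] - poly[i, ]), short = FALSE,
       len = total)
}

#' Measure the bifurcation angle at one junction node
#'
#' Walks `arm_px` of arclength along each of the three incident branches
#' (clamping to the branch end when shorter, with a short-arm flag), forms
#' the three vectors node -> arm point, computes the three sector angles
#' (which sum to 360 deg) and selects the smallest as the candidate
#' bifurcation angle. If a bead circle is attached to the graph the
#' measurement is also classified via [classify_bifurcation()].
#'
#' Thinning a stroke union displaces the skeleton branch point outward from
#' the true apex by about `(w/2)/sin(phi/2)` (w = stroke width), and the
#' skeleton curves near the junction. Vectors taken literally from the node
#' therefore over-read the angle by 5-10 deg at typical sprout widths. The
#' arm vector is instead the branch chord between the polyline points at
#' arclengths `arm_offset_px` and `arm_px`, which skips the curved merge
#' zone; `arm_offset_px = 0` recovers the literal node-to-arm-point rule.
#'
#' @param graph a `skeleton_graph`.
#' @param node_id id of a node with exactly three incident branch ends;
#'   other degrees are skipped (an `angle_skip` record is returned).
#' @param arm_px arm length in pixels (default 60, about 75 um).
#' @param arm_offset_px arclength at which the arm chord starts (default
#'   `arm_px / 4`); clamped to a third of short branches.
#' @return an `angle_measurement` list: `node_id`, `node_xy`, `arm_points`
#'   (3 x 2), `raw_angles_deg` (sector angles), `selected_angle_deg`,
#'   `short_arm_flag`, `classification`, `bisector_angle_to_radial_deg`;
#'   or an `angle_skip` when the node is skipped.
#' @export
measure_node <- function(graph, node_id, arm_px = 60,
                         arm_offset_px = arm_px / 4) {
  nd <- graph$nodes[graph$nodes$id == node_id, , drop = FALSE]
  if (nrow(nd) != 1) stop("unknown node id ", node_id)
  node <- c(nd$x, nd$y)
  ends <- list()
  for (s in graph$segments) {
    if (s$nodes[1] == node_id) ends[[length(ends) + 1L]] <- list(s = s, from_start = TRUE)
    if (s$nodes[2] == node_id) ends[[length(ends) + 1L]] <- list(s = s, from_start = FALSE)
  }
  if (length(ends) != 3L) {
    return(structure(list(node_id = node_id,
                          reason = sprintf("node %s has degree %d, not 3",
                                           node_id, length(ends))),
                     class = "angle_skip"))
  }
  arm <- matrix(NA_real_, 3, 2)
  origin <- matrix(NA_real_, 3, 2)
  short <- logical(3)
  too_short <- FALSE
  for (i in 1:3) {
    poly <- ends[[i]]$s$polyline
    ap <- .arm_point(poly, ends[[i]]$from_start, arm_px)
    off <- min(arm_offset_px, ap$len / 3)
    o <- .arm_point(poly, ends[[i]]$from_start, off)
    arm[i, ] <- ap$point
    origin[i, ] <- o$point
    short[i] <- ap$short
    if (ap$len < 5) too_short <- TRUE
  }
  vec <- arm - origin
  norms <- sqrt(rowSums(vec^2))
  if (any(norms == 0) || too_short) {
    m <- list(node_id = node_id, node_xy = node, arm_points = arm,
              raw_angles_deg = rep(NA_real_, 3),
              selected_angle_deg = NA_real_, short_arm_flag = any(short),
              classification = "indeterminate",
              bisector_angle_to_radial_deg = NA_real_)
    class(m) <- "angle_measurement"
    return(m)
  }
  bearings <- atan2(vec[, 2], vec[, 1])
  ord <- order(bearings)
  b <- bearings[ord]
  sector <- c(diff(b), 2 * pi - (b[3] - b[1])) * 180 / pi
  sel <- which.min(sector)
  selected <- sector[sel]
  # the two arms spanning the selected sector
  pair_idx <- if (sel < 3) ord[c(sel, sel + 1)] else ord[c(3, 1)]
  u <- vec[pair_idx, , drop = FALSE]
  u <- u / norms[pair_idx]
  bis <- colSums(u)
  m <- list(node_id = node_id, node_xy = node, arm_points = arm,
            raw_angles_deg = sector, selected_angle_deg = selected,
            selected_arm_vectors = u, bisector = bis,
            short_arm_flag = any(short),
            classification = "unclassified",
            bisector_angle_to_radial_deg = NA_real_)
  class(m) <- "angle_measurement"
  if (!is.null(graph$bead)) m <- classify_bifurcation(m, graph$bead$center)
  m
}

#' Classify a measured angle as bifurcation or anastomosis
#'
#' The bisector of the selected smallest angle is the normalized sum of the
#' two unit arm vectors. The node is a bifurcation iff the angle between
#' the bisector and the outward radial vector (bead centre -> node) is at
#' most 90 deg (inclusive); otherwise an anastomosis. A zero-length
#' bisector (anti-parallel arms) is indeterminate.
#'
#' @param measure an `angle_measurement` from [measure_node()].
#' @param bead_center numeric `c(x, y)` of the bead centre in pixels.
#' @return the measurement with `classification` and
#'   `bisector_angle_to_radial_deg` filled in.
#' @export
classify_bifurcation <- function(measure, bead_center) {
  if (is.na(measure$selected_angle_deg)) return(measure)
  bis <- measure$bisector
  nb <- sqrt(sum(bis^2))
  if (nb < 1e-9) {
    measure$classification <- "indeterminate"
    return(measure)
  }
  radial <- measure$node_xy - bead_center
  nr <- sqrt(sum(radial^2))
  if (nr == 0) {
    measure$classification <- "indeterminate"
    return(measure)
  }
  cosang <- sum(bis * radial) / (nb * nr)
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  measure$bisector_angle_to_radial_deg <- ang
  measure$classification <- if (ang <= 90) "bifurcation" else "anastomosis"
  measure
}

#' Measure and pool bifurcation angles over a graph
#'
#' Runs [measure_node()] on every degree-3 junction node, keeps the
#' measurements classified as bifurcations, and summarizes them.
#'
#' @param graph a `skeleton_graph` (with a bead circle for classification).
#' @param arm_px arm length in pixels (default 60).
#' @return list with `angles_deg` (selected angles of bifurcations),
#'   `measurements` (all `angle_measurement`s; degree-skipped nodes appear
#'   as `angle_skip` records), `mean_deg`, `sem_deg`, `n`.
#' @export
angle_distribution <- function(graph, arm_px = 60) {
  jn <- graph$nodes$id[graph$nodes$kind == "junction"]
  ms <- list()
  for (nid in jn) {
    m <- measure_node(graph, nid, arm_px = arm_px)
    if (inherits(m, "angle_measurement")) ms[[length(ms) + 1L]] <- m
  }
  keep <- Filter(function(m) identical(m$classification, "bifurcation"), ms)
  angles <- vapply(keep, `[[`, numeric(1), "selected_angle_deg")
  n <- length(angles)
  list(angles_deg = angles, measurements = ms,
       mean_deg = if (n) mean(angles) else NA_real_,
       sem_deg = if (n > 1) stats::sd(angles) / sqrt(n) else if (n == 1) 0 else NA_real_,
       n = n)
}

#' Universal Laplacian branching angle
#'
#' The planar diffusion-limited (Laplacian) growth models predict a
#' universal bifurcation angle of 2*pi/5 radians.
#'
#' @return the angle in degrees (exactly 72).
#' @export
laplacian_reference_angle <- function() {
  (2 * pi / 5) * 180 / pi
}
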