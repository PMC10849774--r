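## Skeletonization of the sprout mask and conversion to an annotated graph:
## nodes are junctions, sprout bases (contact with the bead) or tips;
## segments are maximal skeleton paths between nodes, classed as
## tip / bifurcating / primary.

#' Morphological thinning to a unit-width skeleton
#'
#' Two-subiteration (Zhang–Suen) thinning to convergence; preserves
#' topology and endpoints, returns an 8-connected centerline. A light
#' binary opening applied first suppresses the boundary roughness (noise
#' pimples, blunt-cut corners) that thinning would otherwise turn into
#' spurious short spurs and a wiggly, length-inflating centerline.
#'
#' @param sprout_mask logical matrix.
#' @param smooth_radius_px radius of the pre-thinning binary opening
#'   (default 0 = plain thinning; the batch pipeline uses 2). Must stay
#'   below half the thinnest structure of interest.
#' @return logical matrix of the same shape.
#' @export
skeletonize <- function(sprout_mask, smooth_radius_px = 0) {
  if (!any(sprout_mask)) return(sprout_mask)
  m <- sprout_mask
  if (smooth_radius_px > 0)
    m <- .binary_dilate(.binary_erode(m, smooth_radius_px), smooth_radius_px)
  thin_cpp(m)
}

# orthogonal steps first: path walking must not cut corners across a
# diagonal when an orthogonal neighbour continues the same curve
.offsets8 <- cbind(dr = c(-1, 0, 1, 0, -1, -1, 1, 1),
                   dc = c(0, 1, 0, -1, -1, 1, -1, 1))

# drop redundant staircase corners: an interior vertex whose predecessor and
# successor are themselves 8-adjacent adds a detour the thinning left behind;
# collapsing it yields the minimal 8-chain the sqrt(2) metric assumes
.simplify_chain <- function(xs, ys) {
  repeat {
    n <- length(xs)
    if (n < 3) break
    keep <- rep(TRUE, n)
    i <- 2L
    while (i < n) {
      if (keep[i - 1L] &&
          max(abs(xs[i + 1L] - xs[i - 1L]), abs(ys[i + 1L] - ys[i - 1L])) <= 1) {
        keep[i] <- FALSE
        i <- i + 2L
      } else i <- i + 1L
    }
    if (all(keep)) break
    xs <- xs[keep]; ys <- ys[keep]
  }
  list(x = xs, y = ys)
}

.polyline_length_px <- function(poly) {
  if (nrow(poly) < 2) return(0)
  d <- diff(poly)
  sum(sqrt(d[, 1]^2 + d[, 2]^2))
}

.seg_classes <- function(node_kinds) {
  cls <- if ("tip" %in% node_kinds) "tip" else "bifurcating"
  if ("base" %in% node_kinds) cls <- c(cls, "primary")
  cls
}

.recompute_classes <- function(g) {
  kinds <- stats::setNames(g$nodes$kind, g$nodes$id)
  for (i in seq_along(g$segments)) {
    s <- g$segments[[i]]
    g$segments[[i]]$classes <- .seg_classes(kinds[as.character(s$nodes)])
  }
  g
}

.node_degrees <- function(g) {
  ids <- g$nodes$id
  deg <- stats::setNames(integer(length(ids)), ids)
  for (s in g$segments) {
    for (n in s$nodes) deg[as.character(n)] <- deg[as.character(n)] + 1L
  }
  deg
}

#' Assemble a skeleton graph from explicit nodes and segments
#'
#' Low-level constructor used by [build_graph()] and by synthetic test
#' fixtures. Node kinds must be `junction`, `tip` or `base`; each segment's
#' endpoint ids must exist; classes are derived from endpoint kinds.
#'
#' @param nodes data.frame with columns `id`, `x`, `y`, `kind`.
#' @param segments list of lists with `polyline` (n x 2 matrix of x, y) and
#'   `nodes` (length-2 vector of endpoint node ids, first = polyline start).
#' @param bead a [circle_px()] or NULL.
#' @param resolution_um_per_px um per pixel.
#' @return `skeleton_graph` object.
#' @export
skeleton_graph <- function(nodes, segments, bead = NULL,
                           resolution_um_per_px = 1.25) {
  stopifnot(all(c("id", "x", "y", "kind") %in% names(nodes)))
  if (!all(nodes$kind %in% c("junction", "tip", "base")))
    stop("node kinds must be junction, tip or base")
  segs <- list()
  for (i in seq_along(segments)) {
    s <- segments[[i]]
    if (!all(s$nodes %in% nodes$id))
      stop("segment endpoint refers to unknown node")
    poly <- s$polyline
    colnames(poly) <- c("x", "y")
    segs[[i]] <- list(id = if (!is.null(s$id)) s$id else i,
                      polyline = poly, nodes = s$nodes,
                      length_px = .polyline_length_px(poly))
  }
  names(segs) <- vapply(segs, function(s) as.character(s$id), character(1))
  g <- structure(list(nodes = nodes, segments = segs, bead = bead,
                      resolution_um_per_px = resolution_um_per_px),
                 class = "skeleton_graph")
  .recompute_classes(g)
}

#' @export
print.skeleton_graph <- function(x, ...) {
  kinds <- table(factor(x$nodes$kind, c("junction", "tip", "base")))
  cat(sprintf(
    "<skeleton_graph %d nodes (%d junction, %d tip, %d base), %d segments, L = %.1f um>\n",
    nrow(x$nodes), kinds[["junction"]], kinds[["tip"]], kinds[["base"]],
    length(x$segments), total_length_um(x)))
  invisible(x)
}

#' Total skeleton length in micrometres
#' @param graph a `skeleton_graph`.
#' @return numeric scalar.
#' @export
total_length_um <- function(graph) {
  sum(vapply(graph$segments, function(s) s$length_px, numeric(1))) *
    graph$resolution_um_per_px
}

#' Segment lengths in micrometres, optionally filtered by class
#' @param graph a `skeleton_graph`.
#' @param class optional class filter (`"tip"`, `"bifurcating"`, `"primary"`).
#' @return numeric vector.
#' @export
segment_lengths_um <- function(graph, class = NULL) {
  segs <- graph$segments
  if (!is.null(class))
    segs <- Filter(function(s) class %in% s$classes, segs)
  vapply(segs, function(s) s$length_px, numeric(1)) *
    graph$resolution_um_per_px
}

#' Convert a unit-width skeleton into an annotated graph
#'
#' Pixels with three or more branches form junction nodes (8-adjacent
#' junction pixels merge into one node at their centroid); pixels with one
#' branch are tips, reclassified as sprout bases when the endpoint lies
#' within `base_contact_px` of the bead circle. Branch counts are degrees
#' on the reduced pixel adjacency (diagonal edges shortcut by an orthogonal
#' skeleton neighbour are dropped), which is immune to the staircase
#' patterns of 8-connected thinning. Maximal skeleton paths between nodes
#' become segments; path lengths use the geodesic pixel metric (diagonal
#' steps sqrt(2)). Isolated loops with no junction get an artificial
#' junction node carrying a self-loop segment; self-loops shorter than
#' `min_loop_px` (pinhole thinning artifacts) are discarded; isolated
#' single pixels are dropped.
#'
#' @param skeleton logical matrix (unit-width skeleton).
#' @param bead a [circle_px()] giving the circle against which base contact
#'   is tested (typically detection radius + removal margin), or NULL.
#' @param resolution um per pixel.
#' @param base_contact_px maximal distance between a skeleton endpoint and
#'   the bead circle for base classification (default 10: thinning retracts
#'   the endpoint of a stroke cut at the bead by about half the stroke
#'   width, so the contact tolerance must cover typical sprout half-widths).
#' @param min_loop_px self-loops shorter than this are dropped (default 10).
#' @param sprout_mask optional binary mask the skeleton came from; when
#'   given (with `bead`), endpoints lying in the mask within
#'   `base_reach_px` of the mask's contact arcs with the cleared bead disk
#'   are classified as bases. This is robust to oblique cuts, where
#'   thinning retracts the centerline far beyond `base_contact_px`.
#' @param base_reach_px reach of the contact-region flood (default 30).
#' @return `skeleton_graph`.
#' @export
build_graph <- function(skeleton, bead = NULL, resolution = 1.25,
                        base_contact_px = 10, min_loop_px = 10,
                        sprout_mask = NULL, base_reach_px = 30) {
  nr <- nrow(skeleton); nc <- ncol(skeleton)
  # reduced pixel adjacency: diagonal edges shortcut by an orthogonal
  # neighbour are dropped, so the degree is the true branch count and
  # staircase path pixels stay degree 2
  adj <- reduced_adjacency_cpp(skeleton)
  deg <- matrix(0L, nr, nc)
  for (k in 0:7) deg <- deg + (adj %/% as.integer(2^k)) %% 2L
  junction_px <- skeleton & (deg >= 3L)
  end_px <- skeleton & (deg == 1L)

  node_id_px <- matrix(0L, nr, nc)
  nodes_x <- numeric(0); nodes_y <- numeric(0); nodes_kind <- character(0)
  next_id <- 0L

  # junction clusters -> one node each at rounded centroid
  if (any(junction_px)) {
    lab <- label_components_cpp(junction_px, 8L)
    for (j in seq_len(max(lab))) {
      idx <- which(lab == j, arr.ind = TRUE)
      next_id <- next_id + 1L
      nodes_x[next_id] <- round(mean(idx[, "col"]))
      nodes_y[next_id] <- round(mean(idx[, "row"]))
      nodes_kind[next_id] <- "junction"
      node_id_px[idx] <- next_id
    }
  }
  # contact region: the part of the sprout mask within base_reach_px of its
  # contact arcs with the cleared bead disk. Skeleton endpoints there are
  # sprout bases even when an oblique cut retracts the centerline far from
  # the circle itself.
  base_region <- NULL
  if (!is.null(bead) && !is.null(sprout_mask)) {
    dx <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - bead$center[1]
    dy <- matrix(seq_len(nr), nr, nc) - bead$center[2]
    dd <- sqrt(dx * dx + dy * dy)
    seeds <- sprout_mask & dd > bead$radius & dd <= bead$radius + 2
    if (any(seeds))
      base_region <- sprout_mask & (edt_sq_cpp(seeds) <= base_reach_px^2)
  }
  endpoint_kind <- function(r, c) {
    if (!is.null(base_region) && base_region[r, c]) return("base")
    if (!is.null(bead)) {
      d <- sqrt((c - bead$center[1])^2 + (r - bead$center[2])^2)
      if (abs(d - bead$radius) <= base_contact_px) return("base")
    }
    "tip"
  }
  register_endpoint <- function(r, c) {
    next_id <<- next_id + 1L
    nodes_x[next_id] <<- c; nodes_y[next_id] <<- r
    nodes_kind[next_id] <<- endpoint_kind(r, c)
    node_id_px[r, c] <<- next_id
    next_id
  }
  # endpoints -> tip or base nodes
  if (any(end_px)) {
    idx <- which(end_px, arr.ind = TRUE)
    for (i in seq_len(nrow(idx)))
      register_endpoint(idx[i, "row"], idx[i, "col"])
  }

  adj_dirs <- function(r, c) which(bitwAnd(adj[r, c], bitwShiftL(1L, 0:7)) > 0L)

  visited <- matrix(FALSE, nr, nc)
  segments <- list()
  seg_pairs <- character(0)   # dedupe direct node-node adjacencies
  total_skel <- sum(skeleton)

  trace_from <- function(r0, c0, r1, c1) {
    # walk from node pixel (r0,c0) through non-node pixel (r1,c1) along the
    # reduced adjacency to the next node pixel
    path_r <- c(r0, r1); path_c <- c(c0, c1)
    visited[r1, c1] <<- TRUE
    pr <- r0; pc <- c0; cr <- r1; cc <- c1
    for (step in seq_len(total_skel + 2L)) {
      nbr <- NULL; nbn <- NULL
      for (k in adj_dirs(cr, cc)) {
        rr <- cr + .offsets8[k, 1]; c2 <- cc + .offsets8[k, 2]
        if (rr == pr && c2 == pc) next
        if (node_id_px[rr, c2] > 0L) {
          if (is.null(nbn)) nbn <- c(rr, c2)
        } else if (!visited[rr, c2]) {
          if (is.null(nbr)) nbr <- c(rr, c2)
        }
      }
      if (!is.null(nbn)) {
        path_r <- c(path_r, nbn[1]); path_c <- c(path_c, nbn[2])
        return(list(x = path_c, y = path_r, end = node_id_px[nbn[1], nbn[2]]))
      }
      if (is.null(nbr)) return(list(x = path_c, y = path_r, end = NA_integer_))
      pr <- cr; pc <- cc; cr <- nbr[1]; cc <- nbr[2]
      visited[cr, cc] <<- TRUE
      path_r <- c(path_r, cr); path_c <- c(path_c, cc)
    }
    list(x = path_c, y = path_r, end = NA_integer_)
  }

  node_pixels <- which(node_id_px > 0L, arr.ind = TRUE)
  if (nrow(node_pixels)) {
    ord <- order(node_id_px[node_pixels], node_pixels[, "row"], node_pixels[, "col"])
    node_pixels <- node_pixels[ord, , drop = FALSE]
  }
  add_segment <- function(xs, ys, from, to) {
    sim <- .simplify_chain(xs, ys)
    poly <- cbind(x = sim$x, y = sim$y)
    segments[[length(segments) + 1L]] <<-
      list(id = length(segments) + 1L, polyline = poly,
           nodes = c(from, to), length_px = .polyline_length_px(poly))
  }
  for (i in seq_len(nrow(node_pixels))) {
    r <- node_pixels[i, "row"]; c <- node_pixels[i, "col"]
    nid <- node_id_px[r, c]
    for (k in adj_dirs(r, c)) {
      rr <- r + .offsets8[k, 1]; cc <- c + .offsets8[k, 2]
      oid <- node_id_px[rr, cc]
      if (oid == nid && oid > 0L) next          # same node cluster
      if (oid > 0L) {
        key <- paste(sort(c((r - 1) * nc + c, (rr - 1) * nc + cc)), collapse = "|")
        if (key %in% seg_pairs) next
        seg_pairs <- c(seg_pairs, key)
        add_segment(c(c, cc), c(r, rr), nid, oid)
      } else if (!visited[rr, cc]) {
        tr <- trace_from(r, c, rr, cc)
        end_id <- tr$end
        if (is.na(end_id)) {
          # walk ran into already-consumed pixels (loop artifact): anchor
          # the dangling path with a tip node at its last pixel
          np <- length(tr$x)
          end_id <- register_endpoint(tr$y[np], tr$x[np])
        }
        add_segment(tr$x, tr$y, nid, end_id)
      }
    }
  }

  # isolated cycles: degree-2 pixels never visited and not node pixels
  leftover <- which(skeleton & !visited & node_id_px == 0L & deg >= 2L,
                    arr.ind = TRUE)
  while (nrow(leftover)) {
    r <- leftover[1, "row"]; c <- leftover[1, "col"]
    next_id <- next_id + 1L
    nodes_x[next_id] <- c; nodes_y[next_id] <- r
    nodes_kind[next_id] <- "junction"
    node_id_px[r, c] <- next_id
    started <- FALSE
    for (k in adj_dirs(r, c)) {
      rr <- r + .offsets8[k, 1]; cc <- c + .offsets8[k, 2]
      if (node_id_px[rr, cc] == 0L && !visited[rr, cc]) {
        tr <- trace_from(r, c, rr, cc)
        end_id <- tr$end
        if (is.na(end_id)) {
          np <- length(tr$x)
          end_id <- register_endpoint(tr$y[np], tr$x[np])
        }
        add_segment(tr$x, tr$y, next_id, end_id)
        started <- TRUE
        break
      }
    }
    if (!started) break
    leftover <- which(skeleton & !visited & node_id_px == 0L & deg >= 2L,
                      arr.ind = TRUE)
  }

  # tiny self-loops are thinning artifacts in thick junction zones: drop
  segments <- Filter(function(s)
    !(s$nodes[1] == s$nodes[2] && s$length_px < min_loop_px), segments)

  nodes <- data.frame(id = seq_len(next_id), x = nodes_x, y = nodes_y,
                      kind = nodes_kind, stringsAsFactors = FALSE)
  used <- unique(unlist(lapply(segments, `[[`, "nodes")))
  nodes <- nodes[nodes$id %in% used, , drop = FALSE]
  if (!is.null(bead) && any(skeleton) && !any(nodes$kind == "base"))
    warning("skeleton has no endpoint near the bead: graph has no base nodes")
  g <- skeleton_graph(nodes, segments, bead = bead,
                      resolution_um_per_px = resolution)
  g
}

.remove_segment <- function(g, sid) {
  g$segments[[as.character(sid)]] <- NULL
  used <- unique(unlist(lapply(g$segments, `[[`, "nodes")))
  g$nodes <- g$nodes[g$nodes$id %in% used, , drop = FALSE]
  g
}

.dissolve_degree2 <- function(g) {
  repeat {
    deg <- .node_degrees(g)
    kinds <- stats::setNames(g$nodes$kind, g$nodes$id)
    cand <- names(deg)[deg == 2L & kinds[names(deg)] == "junction"]
    done <- TRUE
    for (nid in cand) {
      n <- as.integer(nid)
      inc <- Filter(function(s) n %in% s$nodes, g$segments)
      if (length(inc) != 2L) next               # self-loop at this node: keep
      a <- inc[[1]]; b <- inc[[2]]
      # orient a to end at n, b to start at n
      if (a$nodes[1] == n) {
        a$polyline <- a$polyline[rev(seq_len(nrow(a$polyline))), , drop = FALSE]
        a$nodes <- rev(a$nodes)
      }
      if (b$nodes[2] == n) {
        b$polyline <- b$polyline[rev(seq_len(nrow(b$polyline))), , drop = FALSE]
        b$nodes <- rev(b$nodes)
      }
      merged <- list(id = a$id,
                     polyline = rbind(a$polyline, b$polyline),
                     nodes = c(a$nodes[1], b$nodes[2]),
                     length_px = a$length_px + b$length_px)
      g$segments[[as.character(a$id)]] <- NULL
      g$segments[[as.character(b$id)]] <- NULL
      g$segments[[as.character(merged$id)]] <- merged
      g$nodes <- g$nodes[g$nodes$id != n, , drop = FALSE]
      done <- FALSE
      break                                      # degrees changed; recompute
    }
    if (done) break
  }
  g
}

#' Prune short tip segments
#'
#' Iteratively removes tip segments whose pixel-path length is below
#' `min_len_px`, except those carrying class `primary` (sprout bases).
#' After each removal, junction nodes left with exactly two incident
#' segments are dissolved by merging the segments (lengths add exactly), and
#' junctions left with one incident segment become tips. Repeats to a fixed
#' point; idempotent.
#'
#' @param graph a `skeleton_graph`.
#' @param min_len_px pruning threshold in pixels (default 50, i.e. 62.5 um
#'   at 1.25 um/px).
#' @return pruned `skeleton_graph`.
#' @export
prune <- function(graph, min_len_px = 50) {
  g <- graph
  repeat {
    g <- .recompute_classes(g)
    doomed <- Filter(function(s)
      "tip" %in% s$classes && !("primary" %in% s$classes) &&
        s$length_px < min_len_px, g$segments)
    if (length(doomed) == 0L) break
    # remove the shortest first for determinism
    lens <- vapply(doomed, `[[`, numeric(1), "length_px")
    sid <- doomed[[order(lens, vapply(doomed, `[[`, numeric(1), "id"))[1]]]$id
    g <- .remove_segment(g, sid)
    # junctions that lost branches: degree 1 -> becomes a tip node
    deg <- .node_degrees(g)
    for (nid in names(deg)[deg == 1L]) {
      sel <- g$nodes$id == as.integer(nid) & g$nodes$kind == "junction"
      g$nodes$kind[sel] <- "tip"
    }
    g <- .dissolve_degree2(g)
  }
  g
}
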