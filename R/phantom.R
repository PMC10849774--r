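## Ground-truthed synthetic bead-sprouting networks: radially outgrowing
## branched sprouts with exponential inter-branch segment lengths,
## quasi-Gaussian bifurcation angles, and a logistic total-length schedule.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

.rot <- function(v, ang) {
  c(cos(ang) * v[1] - sin(ang) * v[2], sin(ang) * v[1] + cos(ang) * v[2])
}

.rtrunc_norm_angle <- function(mean, sd) {
  if (sd <= 0) return(min(max(mean, 1e-6), 180 - 1e-6))
  for (i in 1:10000) {
    x <- stats::rnorm(1, mean, sd)
    if (x > 0 && x < 180) return(x)
  }
  mean
}

#' Logistic growth curve
#'
#' `Y(t) = Y_max / (1 + exp(-k (t - t1)))`: saturation level `Y_max`,
#' exponential-phase rate `k`, inflection day `t1`.
#'
#' @param t time (days), vectorized.
#' @param Y_max saturation level.
#' @param k growth rate (1/day).
#' @param t1 inflection day.
#' @return Y(t).
#' @export
logistic_value <- function(t, Y_max, k, t1) Y_max / (1 + exp(-k * (t - t1)))

#' Phantom specification
#'
#' Defaults describe a realistic high-VEGF bead assay: a 265 um bead, six
#' primary sprouts, exponential inter-branch lengths with mean 100 um,
#' bifurcation angles Normal(70 deg, 18 deg) truncated to (0, 180), 10 um
#' sprout width, and a logistic total-length schedule (Y_max = 4000 um,
#' k = 1.2/day, t1 = 7 d) sampled daily over days 0..14.
#'
#' @param bead_radius_um bead radius (default 132.5).
#' @param n_primary number of primary branches (default 6).
#' @param mean_segment_length_um expected inter-branch distance l* (default 100).
#' @param branch_angle_mean_deg,branch_angle_sd_deg bifurcation-angle
#'   distribution (default 70, 18).
#' @param sprout_width_um rendered stroke width (default 10).
#' @param tip_speed_um_per_day per-tip elongation cap (default 100).
#' @param direction_noise_deg per-step (1 px arclength) angular jitter sd
#'   (default 1).
#' @param drift_weight blending weight of the outward radial direction per
#'   step (default 0.0002: weak enough that sprout curvature over a 60 px
#'   angle-measurement arm biases the measured angle by under a degree;
#'   see the methods vignette).
#' @param logistic_params list `(Y_max, k, t1)` for the total-length
#'   schedule in um and days.
#' @param days day grid (default 0:14).
#' @param image_size_px square frame side (default 1024).
#' @param resolution_um_per_px calibration (default 1.25).
#' @param noise_sd additive Gaussian image noise, 16-bit counts (default 100).
#' @param background_level,foreground_level rendered intensities (defaults
#'   2000 and 3200; modest GFP-like contrast, see vignette).
#' @param min_primary_gap_deg minimum angular separation between primary
#'   bases on the rim (default 20; 0 recovers pure uniform placement).
#' @param min_branch_arclength_um a tip may bifurcate only after its
#'   current segment has grown this long (default 0 = memoryless Poisson
#'   branching). Well-separated-branch fixtures set this to a few sprout
#'   widths so forks and bases never overlap below the pixel resolution.
#' @param branch_until_day bifurcations stop after this day (default Inf).
#'   Freezing the topology before the last measured day lets every leaf
#'   elongate past the pruning scale, making ground-truth counts
#'   unambiguous for round-trip validation.
#' @param avoid_collisions terminate tips approaching foreign sprouts, so
#'   the rendered image stays anastomosis-free (default TRUE).
#' @param retract_stubs_um a tip terminated (collision or frame) before
#'   reaching this length retracts completely, like the regressing failed
#'   sprouts seen in real assays (default 0 = keep all stubs). Round-trip
#'   fixtures set it just above the pruning scale: a stub straddling that
#'   scale is undecidable for any pixel pipeline.
#' @param rng_seed integer seed (default 1).
#' @return `phantom_spec` object.
#' @export
phantom_spec <- function(bead_radius_um = 132.5, n_primary = 6,
                         mean_segment_length_um = 100,
                         branch_angle_mean_deg = 70, branch_angle_sd_deg = 18,
                         sprout_width_um = 10, tip_speed_um_per_day = 100,
                         direction_noise_deg = 1, drift_weight = 0.0002,
                         logistic_params = list(Y_max = 4000, k = 1.2, t1 = 7),
                         days = 0:14, image_size_px = 1024,
                         resolution_um_per_px = 1.25, noise_sd = 100,
                         background_level = 2000, foreground_level = 3200,
                         min_primary_gap_deg = 20,
                         min_branch_arclength_um = 0,
                         branch_until_day = Inf, avoid_collisions = TRUE,
                         retract_stubs_um = 0, rng_seed = 1) {
  spec <- list(bead_radius_um = bead_radius_um, n_primary = as.integer(n_primary),
               mean_segment_length_um = mean_segment_length_um,
               branch_angle_mean_deg = branch_angle_mean_deg,
               branch_angle_sd_deg = branch_angle_sd_deg,
               sprout_width_um = sprout_width_um,
               tip_speed_um_per_day = tip_speed_um_per_day,
               direction_noise_deg = direction_noise_deg,
               drift_weight = drift_weight,
               logistic_params = logistic_params, days = days,
               image_size_px = as.integer(image_size_px),
               resolution_um_per_px = resolution_um_per_px,
               noise_sd = noise_sd, background_level = background_level,
               foreground_level = foreground_level,
               min_primary_gap_deg = min_primary_gap_deg,
               min_branch_arclength_um = min_branch_arclength_um,
               branch_until_day = branch_until_day,
               avoid_collisions = isTRUE(avoid_collisions),
               retract_stubs_um = retract_stubs_um,
               rng_seed = as.integer(rng_seed))
  with(spec, {
    stopifnot(bead_radius_um > 0, n_primary >= 0, mean_segment_length_um > 0,
              sprout_width_um > 0, tip_speed_um_per_day > 0,
              resolution_um_per_px > 0, image_size_px > 0,
              logistic_params$k > 0, logistic_params$Y_max > 0,
              noise_sd >= 0, length(days) >= 1)
  })
  structure(spec, class = "phantom_spec")
}

#' Generate a ground-truthed sprouting network
#'
#' Primary sprouts start on the bead rim at uniformly drawn angles (subject
#' to a minimum gap) and advance outward in 1 px arclength steps with
#' Gaussian angular jitter plus a weak radial restoring drift. Each active
#' tip bifurcates as a Poisson process with rate `1/l*` per unit arclength;
#' at a bifurcation the two daughters deviate +/- phi/2 from the parent
#' direction, phi ~ Normal(mean, sd) truncated to (0, 180) deg. Growth is
#' scheduled so that cumulative length tracks the logistic schedule, capped
#' by the per-tip speed. Identical spec + seed gives identical output.
#'
#' @param spec a [phantom_spec()].
#' @return `phantom_network`: bead geometry, segment list (polylines in
#'   pixel coordinates, parentage, generation, class, length), per-day
#'   snapshots (visible point counts per segment), and the ground-truth
#'   bifurcation angles actually drawn.
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  res <- spec$resolution_um_per_px
  size <- spec$image_size_px
  center <- c((size + 1) / 2, (size + 1) / 2)
  bead_r <- spec$bead_radius_um / res
  width_px <- spec$sprout_width_um / res
  margin <- max(2, ceiling(width_px))
  if (bead_r + 2 >= size / 2)
    stop("geometry error: bead does not leave room for a primary sprout")
  p_branch <- res / spec$mean_segment_length_um    # per 1-px step
  cap_px <- spec$tip_speed_um_per_day / res
  # clearance must keep rendered stroke surfaces apart even after the
  # segmentation blur dilates them by ~2-3 px each: 2.5 widths leaves a
  # >= 1.5 width surface gap
  clearance <- 2.5 * width_px

  .with_seed(spec$rng_seed, {
    # primary base angles: uniform with a minimum circular gap
    if (spec$n_primary > 0) {
      gap <- spec$min_primary_gap_deg * pi / 180
      for (att in 1:1000) {
        th <- sort(stats::runif(spec$n_primary, 0, 2 * pi))
        gaps <- if (spec$n_primary > 1)
          c(diff(th), 2 * pi - (th[spec$n_primary] - th[1])) else 2 * pi
        if (all(gaps >= gap)) break
        if (att == 1000) stop("could not place primaries with the requested gap")
      }
    } else th <- numeric(0)

    segs <- list()        # per-segment state; polyline buffers grow by doubling
    occ <- matrix(0L, size, size)
    new_seg <- function(origin, dir, parent, generation, sibling = NA_integer_) {
      id <- length(segs) + 1L
      pts <- matrix(NA_real_, 256L, 2)
      pts[1, ] <- origin
      segs[[id]] <<- list(id = id, pts = pts, n = 1L, dir = dir,
                          parent = parent, sibling = sibling,
                          generation = generation, children = integer(0),
                          status = "active", day_steps = 0)
      id
    }
    for (i in seq_along(th)) {
      u <- c(cos(th[i]), sin(th[i]))
      new_seg(center + bead_r * u, u, NA_integer_, 1L)
    }

    angles_drawn <- numeric(0)
    total_steps <- 0
    current_day <- spec$days[1]
    retract_px <- spec$retract_stubs_um / res

    terminate <- function(id) {
      s <- segs[[id]]
      if (retract_px > 0 && (s$n - 1L) < retract_px) {
        # failed stub: retract fully, release its budget and occupancy
        for (j in seq_len(s$n)[-1]) {
          rr <- round(s$pts[j, 2]); cc <- round(s$pts[j, 1])
          if (occ[rr, cc] == id) occ[rr, cc] <<- 0L
        }
        total_steps <<- total_steps - (s$n - 1L)
        segs[[id]]$n <<- 1L
        segs[[id]]$status <<- "retracted"
      } else {
        segs[[id]]$status <<- "terminated"
      }
    }

    advance <- function(id) {
      s <- segs[[id]]
      pos <- s$pts[s$n, ]
      radial <- pos - center
      nr <- sqrt(sum(radial^2))
      radial <- if (nr > 0) radial / nr else s$dir
      dir <- (1 - spec$drift_weight) * s$dir + spec$drift_weight * radial
      dir <- dir / sqrt(sum(dir^2))
      dir <- .rot(dir, stats::rnorm(1, 0, spec$direction_noise_deg * pi / 180))
      cand <- pos + dir
      if (cand[1] < margin || cand[1] > size - margin ||
          cand[2] < margin || cand[2] > size - margin) {
        terminate(id)
        return(FALSE)
      }
      if (spec$avoid_collisions) {
        cr <- round(cand[2]); cc <- round(cand[1])
        rad <- ceiling(clearance)
        r0 <- max(1, cr - rad); r1 <- min(size, cr + rad)
        c0 <- max(1, cc - rad); c1 <- min(size, cc + rad)
        win <- occ[r0:r1, c0:c1]
        hit <- unique(win[win != 0L])
        gp <- if (!is.na(s$parent)) segs[[s$parent]]$parent else NA_integer_
        allowed <- c(id, s$parent, s$sibling, gp)
        foreign <- setdiff(hit, allowed[!is.na(allowed)])
        if (length(foreign)) {
          # verify true distance below clearance before terminating
          close_hit <- FALSE
          for (f in foreign) {
            idxs <- which(win == f, arr.ind = TRUE)
            dy <- (r0 + idxs[, 1] - 1) - cand[2]
            dx <- (c0 + idxs[, 2] - 1) - cand[1]
            if (any(dx * dx + dy * dy <= clearance^2)) { close_hit <- TRUE; break }
          }
          if (close_hit) {
            terminate(id)
            return(FALSE)
          }
        }
      }
      n <- s$n + 1L
      if (n > nrow(segs[[id]]$pts))
        segs[[id]]$pts <<- rbind(segs[[id]]$pts,
                                 matrix(NA_real_, nrow(segs[[id]]$pts), 2))
      segs[[id]]$pts[n, ] <<- cand
      segs[[id]]$n <<- n
      segs[[id]]$dir <<- dir
      segs[[id]]$day_steps <<- s$day_steps + 1
      rr <- round(cand[2]); cc2 <- round(cand[1])
      if (occ[rr, cc2] == 0L) occ[rr, cc2] <<- id
      total_steps <<- total_steps + 1
      # stochastic bifurcation (suppressed during the refractory arclength
      # and after the topology-freeze day)
      can_branch <- current_day <= spec$branch_until_day &&
        (n - 1L) * res >= spec$min_branch_arclength_um
      if (can_branch && stats::runif(1) < p_branch) {
        phi <- .rtrunc_norm_angle(spec$branch_angle_mean_deg,
                                  spec$branch_angle_sd_deg)
        angles_drawn <<- c(angles_drawn, phi)
        half <- phi / 2 * pi / 180
        d1 <- .rot(segs[[id]]$dir, half)
        d2 <- .rot(segs[[id]]$dir, -half)
        g <- segs[[id]]$generation + 1L
        c1id <- new_seg(cand, d1, id, g)
        c2id <- new_seg(cand, d2, id, g, sibling = c1id)
        segs[[c1id]]$sibling <<- c2id
        segs[[c1id]]$day_steps <<- segs[[id]]$day_steps
        segs[[c2id]]$day_steps <<- segs[[id]]$day_steps
        segs[[id]]$children <<- c(c1id, c2id)
        segs[[id]]$status <<- "branched"
      }
      TRUE
    }

    snapshots <- vector("list", length(spec$days))
    names(snapshots) <- as.character(spec$days)
    lp <- spec$logistic_params
    for (di in seq_along(spec$days)) {
      d <- spec$days[di]
      current_day <- d
      for (i in seq_along(segs)) segs[[i]]$day_steps <- 0
      target_steps <- logistic_value(d, lp$Y_max, lp$k, lp$t1) / res
      guard <- 0L
      while (total_steps < floor(target_steps)) {
        act <- which(vapply(segs, function(s)
          s$status == "active" && s$day_steps < cap_px, logical(1)))
        if (!length(act)) break
        progressed <- FALSE
        for (id in act) {
          if (total_steps >= floor(target_steps)) break
          if (segs[[id]]$status == "active" && segs[[id]]$day_steps < cap_px)
            progressed <- advance(id) || progressed
        }
        guard <- guard + 1L
        if (!progressed || guard > 100000L) break
      }
      snapshots[[di]] <- vapply(segs, `[[`, integer(1), "n")
    }

    segments <- lapply(segs, function(s) {
      cls <- if (length(s$children)) "bifurcating" else "tip"
      if (s$generation == 1L) cls <- c(cls, "primary")
      list(id = s$id, parent = s$parent, generation = s$generation,
           children = s$children,
           polyline = s$pts[seq_len(s$n), , drop = FALSE],
           class = cls, status = s$status,
           length_um = (s$n - 1L) * res)
    })
    structure(list(spec = spec, bead_center_px = center,
                   bead_radius_px = bead_r, segments = segments,
                   snapshots = snapshots, days = spec$days,
                   bifurcation_angles_deg = angles_drawn),
              class = "phantom_network")
  })
}

#' @export
print.phantom_network <- function(x, ...) {
  cat(sprintf("<phantom_network %d segments, %d bifurcations, L = %.0f um at day %s>\n",
              length(x$segments), length(x$bifurcation_angles_deg),
              sum(vapply(x$segments, `[[`, numeric(1), "length_um")),
              max(x$days)))
  invisible(x)
}

#' Ground-truth morphometrics of a phantom at a given day
#'
#' Applies the same tip-pruning rule as the measurement pipeline to the
#' ground-truth tree (leaves shorter than `min_len_um` removed unless
#' primary; pass-through parents merged), then counts tips, primaries and
#' total length. This is the reference the pipeline's measurements are
#' compared against.
#'
#' @param net a `phantom_network`.
#' @param day a day present in the network's snapshots.
#' @param min_len_um pruning threshold in um (default 62.5); 0 disables.
#' @return list with `L_um`, `N_tip`, `N_pb`, `G`, `r_max_um` (from the
#'   bead centre to the farthest visible tip).
#' @export
ground_truth_metrics <- function(net, day, min_len_um = 62.5) {
  key <- as.character(day)
  if (!key %in% names(net$snapshots)) stop("no snapshot for day ", day)
  n_at <- net$snapshots[[key]]
  res <- net$spec$resolution_um_per_px
  k <- length(n_at)
  len <- pmax(0, n_at - 1) * res
  present <- n_at >= 2
  parent <- vapply(net$segments[seq_len(k)], function(s)
    ifelse(is.na(s$parent), 0L, s$parent), integer(1))
  gen <- vapply(net$segments[seq_len(k)], `[[`, integer(1), "generation")
  alive <- present
  children_of <- function(i) which(alive & parent == i)
  if (min_len_um > 0) {
    repeat {
      changed <- FALSE
      leaves <- which(alive & vapply(seq_len(k), function(i)
        length(children_of(i)) == 0L, logical(1)))
      doom <- leaves[len[leaves] < min_len_um & gen[leaves] > 1L]
      if (length(doom)) { alive[doom] <- FALSE; changed <- TRUE }
      # dissolve pass-through parents (exactly one surviving child)
      for (i in which(alive)) {
        ch <- children_of(i)
        if (length(ch) == 1L) {
          len[i] <- len[i] + len[ch]
          # graft grandchildren onto i
          parent[parent == ch] <- i
          alive[ch] <- FALSE
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  leaves <- which(alive & vapply(seq_len(k), function(i)
    length(children_of(i)) == 0L, logical(1)))
  n_pb <- sum(alive & gen == 1L)
  n_tip <- length(leaves)
  g_val <- if (n_tip > 0 && n_pb > 0) 1 + log2(n_tip / n_pb) else NA_real_
  r_max <- 0
  for (i in which(alive)) {
    s <- net$segments[[i]]
    p <- s$polyline[min(n_at[i], nrow(s$polyline)), ]
    r_max <- max(r_max, sqrt(sum((p - net$bead_center_px)^2)))
  }
  list(L_um = sum(len[alive]), N_tip = n_tip, N_pb = n_pb, G = g_val,
       r_max_um = r_max * res)
}

#' Render a phantom day as a calibrated image
#'
#' Draws the bead as a filled disk and each visible segment as a stroke of
#' the spec's sprout width at the foreground level over a uniform
#' background, adds Gaussian noise, and clamps to the 16-bit range.
#'
#' @param net a `phantom_network`.
#' @param spec the generating [phantom_spec()] (defaults to `net$spec`).
#' @param day a day with a snapshot.
#' @param noise_seed seed for the additive noise (default derived from the
#'   spec seed and the day, so frames differ but reproduce).
#' @param bead_id bead label stamped into the image metadata.
#' @return [calibrated_image()].
#' @export
render_image <- function(net, spec = net$spec, day,
                         noise_seed = spec$rng_seed * 1000L + which(net$days == day),
                         bead_id = 1L) {
  key <- as.character(day)
  if (!key %in% names(net$snapshots)) stop("no snapshot for day ", day)
  n_at <- net$snapshots[[key]]
  size <- spec$image_size_px
  res <- spec$resolution_um_per_px
  canvas <- matrix(spec$background_level, size, size)
  canvas <- stamp_disks_cpp(canvas, net$bead_center_px[1], net$bead_center_px[2],
                            net$bead_radius_px, spec$foreground_level)
  half_w <- spec$sprout_width_um / res / 2
  for (i in seq_along(net$segments)) {
    n <- if (i <= length(n_at)) n_at[i] else 0L
    if (n < 2) next
    poly <- net$segments[[i]]$polyline[seq_len(n), , drop = FALSE]
    canvas <- stamp_disks_cpp(canvas, poly[, 1], poly[, 2], half_w,
                              spec$foreground_level)
  }
  if (spec$noise_sd > 0) {
    canvas <- .with_seed(as.integer(noise_seed) %% .Machine$integer.max,
                         canvas + matrix(stats::rnorm(size * size, 0, spec$noise_sd),
                                         size, size))
  }
  canvas <- pmin(pmax(canvas, 0), 65535)
  calibrated_image(canvas, resolution_um_per_px = res, bead_id = bead_id,
                   day = day)
}

#' Ground-truth foreground mask of a phantom day
#'
#' Rasterizes the stroke geometry (and optionally the bead disk) at the
#' spec's sprout width; the reference for intersection-over-union checks.
#'
#' @inheritParams render_image
#' @param include_bead include the bead disk (default TRUE).
#' @return logical matrix.
#' @export
ground_truth_mask <- function(net, spec = net$spec, day, include_bead = TRUE) {
  key <- as.character(day)
  n_at <- net$snapshots[[key]]
  size <- spec$image_size_px
  res <- spec$resolution_um_per_px
  out <- matrix(FALSE, size, size)
  if (include_bead)
    out <- out | stamp_mask_cpp(size, size, net$bead_center_px[1],
                                net$bead_center_px[2], net$bead_radius_px)
  half_w <- spec$sprout_width_um / res / 2
  for (i in seq_along(net$segments)) {
    n <- if (i <= length(n_at)) n_at[i] else 0L
    if (n < 2) next
    poly <- net$segments[[i]]$polyline[seq_len(n), , drop = FALSE]
    out <- out | stamp_mask_cpp(size, size, poly[, 1], poly[, 2], half_w)
  }
  out
}

#' Sample a logistic time series with additive noise
#'
#' @param Y_max saturation level.
#' @param k growth rate (1/day), must be positive.
#' @param t1 inflection day.
#' @param days day grid (non-empty).
#' @param noise_sd additive Gaussian noise sd (default 0).
#' @param rng_seed optional seed.
#' @param observable,units metadata for the returned series.
#' @return [time_series()].
#' @export
generate_logistic_series <- function(Y_max, k, t1, days, noise_sd = 0,
                                     rng_seed = NULL, observable = "L",
                                     units = "um") {
  if (k <= 0) stop("k must be positive")
  if (length(days) == 0) stop("empty day grid")
  y <- logistic_value(days, Y_max, k, t1)
  if (noise_sd > 0)
    y <- .with_seed(rng_seed, y + stats::rnorm(length(days), 0, noise_sd))
  time_series(days, y, observable = observable, units = units)
}

#' Export phantom ground truth and frames
#'
#' Writes the ground-truth network as JSON (segments as pixel polylines plus
#' metadata) and each requested day as a single-page 16-bit TIFF named
#' `bead<id>_day<d>.tif`.
#'
#' @param net a `phantom_network`.
#' @param dir output directory (created if needed).
#' @param bead_id bead label used in file names (default 1).
#' @param days days to render (default all snapshot days).
#' @return invisibly, the list of written file paths.
#' @export
export_phantom <- function(net, dir, bead_id = 1L, days = net$days) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt <- list(
    bead_center_px = net$bead_center_px,
    bead_radius_px = net$bead_radius_px,
    resolution_um_per_px = net$spec$resolution_um_per_px,
    days = net$days,
    bifurcation_angles_deg = net$bifurcation_angles_deg,
    segments = lapply(net$segments, function(s)
      list(id = s$id, parent = s$parent, generation = s$generation,
           class = s$class, length_um = s$length_um,
           polyline = unname(s$polyline))),
    snapshots = net$snapshots)
  gt_path <- file.path(dir, sprintf("bead%d_groundtruth.json", bead_id))
  jsonlite::write_json(gt, gt_path, auto_unbox = TRUE, digits = NA, na = "null")
  paths <- gt_path
  for (d in days) {
    img <- render_image(net, day = d, bead_id = bead_id)
    p <- file.path(dir, sprintf("bead%d_day%d.tif", bead_id, d))
    write_tiff(img$pixels, p, bits = 16)
    paths <- c(paths, p)
  }
  invisible(paths)
}
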