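## Global per-bead per-day metrics: areas, total length, mean width, tip
## counts, primary branches, generation number, maximal tip radius — and the
## ensemble tip velocity over a time series.

#' Compute the morphometric record of one segmented, graphed image
#'
#' * `A_um2`   — sprout-mask pixel count x resolution^2 (area outside the bead)
#' * `Ac_um2`  — foreground-within-bead-disk pixel count x resolution^2
#' * `L_um`    — sum of skeleton segment lengths (geodesic pixel metric)
#' * `lambda_um` — mean sprout width A / L (`NA` when L = 0)
#' * `rmax_um` — max distance from the bead centre to a tip node
#' * `N_tip`, `N_pb` — tip-node and primary-segment counts
#' * `G`       — 1 + log2(N_tip / N_pb) (`NA` when either count is 0)
#'
#' @param seg a `segmentation_result` from [segment_bead_image()].
#' @param graph the (pruned) `skeleton_graph` of the same image.
#' @param bead_id,day,condition metadata copied into the record.
#' @param rmax_from_surface if TRUE, subtract the bead radius from `rmax_um`
#'   (default FALSE: radial coordinate measured from the bead centre).
#' @return one-row data.frame with the record schema.
#' @export
compute_record <- function(seg, graph, bead_id = NA, day = NA, condition = "",
                           rmax_from_surface = FALSE) {
  res <- graph$resolution_um_per_px
  a_um2 <- sum(seg$sprout_mask) * res^2
  ac_um2 <- sum(seg$bead_foreground) * res^2
  l_um <- total_length_um(graph)
  lambda <- if (l_um > 0) a_um2 / l_um else NA_real_
  tips <- graph$nodes[graph$nodes$kind == "tip", , drop = FALSE]
  n_tip <- nrow(tips)
  n_pb <- sum(vapply(graph$segments, function(s) "primary" %in% s$classes,
                     logical(1)))
  g_val <- if (n_tip > 0 && n_pb > 0) 1 + log2(n_tip / n_pb) else NA_real_
  r_max <- NA_real_
  if (n_tip > 0 && !is.null(graph$bead)) {
    d <- sqrt((tips$x - graph$bead$center[1])^2 +
              (tips$y - graph$bead$center[2])^2)
    r_max <- max(d) * res
    if (rmax_from_surface) r_max <- max(0, r_max - graph$bead$radius * res)
  }
  data.frame(bead_id = bead_id, day = day, condition = condition,
             A_um2 = a_um2, Ac_um2 = ac_um2, L_um = l_um,
             lambda_um = lambda, rmax_um = r_max,
             N_tip = as.integer(n_tip), N_pb = as.integer(n_pb), G = g_val,
             stringsAsFactors = FALSE)
}

#' Ensemble tip velocity over a time series
#'
#' Per consecutive-day pair, `v = (L(d) - L(d-1)) / (dt * N_tip(d))` — the
#' length increment is attributed to the tips present at the later day —
#' followed by a trailing moving average over `window_days` values. Days
#' with `N_tip = 0` yield `NA`.
#'
#' @param series_L [time_series()] of total length (um).
#' @param series_Ntip [time_series()] of tip counts on the same day grid.
#' @param window_days trailing moving-average window (default 2).
#' @return data.frame with `day`, `v_raw`, `v_tip` (um/day); attribute
#'   `window_days`.
#' @export
tip_velocity <- function(series_L, series_Ntip, window_days = 2) {
  if (!identical(series_L$day, series_Ntip$day))
    stop("L and N_tip series must share the same day grid")
  d <- series_L$day
  if (length(d) < 2) stop("need at least two days")
  dL <- diff(series_L$value)
  dt <- diff(d)
  ntip <- series_Ntip$value[-1]
  v <- ifelse(ntip > 0, dL / (dt * ntip), NA_real_)
  sm <- numeric(length(v))
  for (i in seq_along(v)) {
    lo <- max(1, i - window_days + 1)
    sm[i] <- mean(v[lo:i], na.rm = FALSE)
  }
  out <- data.frame(day = d[-1], v_raw = v, v_tip = sm)
  attr(out, "window_days") <- window_days
  out
}
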