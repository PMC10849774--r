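## Batch orchestration: per (bead, day) segmentation -> graph -> record ->
## angles; per bead growth fits and velocity; aggregate CSV/JSON outputs
## with a structured log and a reproducible configuration.

#' Pipeline run configuration
#'
#' Every stage parameter defaults to the calibrated value for 1.25 um/px
#' acquisitions; all are overridable per run.
#'
#' @param input optional input directory of TIFF stacks (NULL for phantom
#'   mode).
#' @param pattern file-name PCRE with named groups `bead` and `day`.
#' @param resolution um per pixel.
#' @param blur_kernel_px,threshold_factor,hole_perimeter_px,bead_radius_um,
#'   bead_margin_px segmentation-stage parameters.
#' @param prune_length_px,base_contact_px,skeleton_smooth_px graph-stage
#'   parameters.
#' @param arm_length_px angle-measurement arm length.
#' @param bin_width_um,min_length_um segment-length histogram parameters.
#' @param velocity_window_days trailing moving-average window.
#' @param phantom_beads number of phantom beads (phantom mode).
#' @param phantom_spec_args named list of [phantom_spec()] overrides.
#' @param rng_seed base seed for phantom mode.
#' @param out output directory.
#' @return a `run_config` list.
#' @export
run_config <- function(input = NULL,
                       pattern = "bead(?P<bead>\\d+)_day(?P<day>\\d+)",
                       resolution = 1.25, blur_kernel_px = 11,
                       threshold_factor = 1.17, hole_perimeter_px = 200,
                       bead_radius_um = 132.5, bead_margin_px = 2,
                       prune_length_px = 50, base_contact_px = 10,
                       skeleton_smooth_px = 2,
                       arm_length_px = 60, bin_width_um = 25,
                       min_length_um = 62.5, velocity_window_days = 2,
                       phantom_beads = 2, phantom_spec_args = list(),
                       rng_seed = 1, out = tempfile("sproutgraph_run")) {
  cfg <- list(input = input, pattern = pattern, resolution = resolution,
              blur_kernel_px = blur_kernel_px,
              threshold_factor = threshold_factor,
              hole_perimeter_px = hole_perimeter_px,
              bead_radius_um = bead_radius_um,
              bead_margin_px = bead_margin_px,
              prune_length_px = prune_length_px,
              base_contact_px = base_contact_px,
              skeleton_smooth_px = skeleton_smooth_px,
              arm_length_px = arm_length_px, bin_width_um = bin_width_um,
              min_length_um = min_length_um,
              velocity_window_days = velocity_window_days,
              phantom_beads = phantom_beads,
              phantom_spec_args = phantom_spec_args,
              rng_seed = rng_seed, out = out)
  class(cfg) <- "run_config"
  cfg
}

#' FNV-1a hash of a configuration (or any R object)
#'
#' Stable 32-bit hex digest of the deparsed object; stamped into every
#' output artifact so results can be traced to the configuration that
#' produced them.
#'
#' @param x object to hash.
#' @return 8-character hex string.
#' @export
config_hash <- function(x) {
  if (inherits(x, "run_config")) x$out <- NULL    # path does not affect results
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte (h stays a double below 2^32)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit overflow-safe multiply by the FNV prime 16777619 = 403 * 41621
    h <- (h * 403) %% 4294967296
    h <- (h * 41621) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write / read a flat key=value configuration file
#'
#' Round-trips a [run_config()] losslessly through a line-oriented text
#' format (`key = value`; list values deparsed).
#'
#' @param cfg a `run_config`.
#' @param path file path.
#' @return `path` (write) or a `run_config` (read).
#' @export
write_run_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k)
    sprintf("%s = %s", k, paste(deparse(cfg[[k]]), collapse = " ")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  cfg <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed config line: ", ln)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    cfg[[key]] <- eval(parse(text = val), envir = baseenv())
  }
  do.call(run_config, cfg)
}

#' Process one calibrated image through the measurement chain
#'
#' segmentation -> skeletonization -> graph -> pruning -> record + angles.
#'
#' @param img a [calibrated_image()].
#' @param cfg a [run_config()].
#' @param condition condition label stored in the record.
#' @return list with `record` (one-row data.frame), `angles` (data.frame of
#'   per-node measurements), `seg`, `graph`.
#' @export
process_image <- function(img, cfg = run_config(), condition = "") {
  seg <- segment_bead_image(img,
                            blur_kernel_px = cfg$blur_kernel_px,
                            threshold_factor = cfg$threshold_factor,
                            max_perimeter_px = cfg$hole_perimeter_px,
                            expected_radius_um = cfg$bead_radius_um,
                            margin_px = cfg$bead_margin_px)
  skel <- skeletonize(seg$sprout_mask, smooth_radius_px = cfg$skeleton_smooth_px)
  contact_circle <- circle_px(seg$bead$center, seg$removal_radius_px)
  graph <- suppressWarnings(
    build_graph(skel, bead = contact_circle,
                resolution = img$resolution_um_per_px,
                base_contact_px = cfg$base_contact_px,
                sprout_mask = seg$sprout_mask))
  graph <- prune(graph, min_len_px = cfg$prune_length_px)
  record <- compute_record(seg, graph, bead_id = img$bead_id, day = img$day,
                           condition = condition)
  dist <- angle_distribution(graph, arm_px = cfg$arm_length_px)
  ang <- do.call(rbind, lapply(dist$measurements, function(m)
    data.frame(bead_id = img$bead_id, day = img$day, node_id = m$node_id,
               x_px = m$node_xy[1], y_px = m$node_xy[2],
               angle_deg = m$selected_angle_deg,
               classification = m$classification,
               short_arm_flag = m$short_arm_flag,
               stringsAsFactors = FALSE)))
  if (is.null(ang))
    ang <- data.frame(bead_id = integer(0), day = integer(0),
                      node_id = integer(0), x_px = numeric(0),
                      y_px = numeric(0), angle_deg = numeric(0),
                      classification = character(0),
                      short_arm_flag = logical(0))
  list(record = record, angles = ang, seg = seg, graph = graph)
}

#' Run the batch pipeline
#'
#' In input mode, every TIFF under `cfg$input` matching the file pattern is
#' processed; a failing image is logged and skipped without aborting the
#' batch. In phantom mode (`cfg$input` NULL), `cfg$phantom_beads` networks
#' are generated with seeds `rng_seed + bead - 1` and their rendered days
#' processed. Per bead, logistic fits of L(t) and A(t) and the tip-velocity
#' series are computed; segment-length distributions are fitted pooled by
#' segment class over the final day. Outputs under `cfg$out`: records.csv,
#' angles.csv, fits.json, summary.csv, run.log, manifest.json (every file
#' listed with the configuration hash).
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with `records`, `angles`, `fits`, `summary`,
#'   `n_failed`, `out`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  log_lines <- character(0)
  logmsg <- function(level, fmt, ...) {
    line <- sprintf("[%s] %s", level, sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
  }
  logmsg("INFO", "config hash %s", hash)
  for (k in setdiff(names(cfg), "phantom_spec_args"))
    logmsg("INFO", "param %s = %s", k, paste(deparse(cfg[[k]]), collapse = " "))

  records <- list(); angles <- list(); graphs <- list()
  n_failed <- 0L

  handle <- function(img, label) {
    res <- tryCatch(process_image(img, cfg), error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <<- n_failed + 1L
      logmsg("WARN", "skipped %s: %s", label, conditionMessage(res))
      return(invisible(NULL))
    }
    records[[length(records) + 1L]] <<- res$record
    angles[[length(angles) + 1L]] <<- res$angles
    graphs[[label]] <<- res$graph
    logmsg("INFO", "processed %s: L = %.1f um, N_tip = %d", label,
           res$record$L_um, res$record$N_tip)
  }

  if (!is.null(cfg$input)) {
    files <- sort(list.files(cfg$input, pattern = "\\.tiff?$",
                             full.names = TRUE, ignore.case = TRUE))
    if (!length(files)) stop("no TIFF inputs found under ", cfg$input)
    for (f in files) {
      img <- tryCatch(load_stack(f, resolution = cfg$resolution,
                                 pattern = cfg$pattern),
                      error = function(e) e)
      if (inherits(img, "error")) {
        n_failed <- n_failed + 1L
        logmsg("WARN", "skipped %s: %s", basename(f), conditionMessage(img))
        next
      }
      handle(img, basename(f))
    }
  } else {
    if (cfg$phantom_beads < 1) stop("no inputs: phantom_beads < 1")
    for (b in seq_len(cfg$phantom_beads)) {
      sp_args <- cfg$phantom_spec_args
      sp_args$rng_seed <- cfg$rng_seed + b - 1L
      sp <- do.call(phantom_spec, sp_args)
      net <- generate_network(sp)
      for (d in net$days) {
        if (logistic_value(d, sp$logistic_params$Y_max, sp$logistic_params$k,
                           sp$logistic_params$t1) < 2 * cfg$min_length_um &&
            d < sp$logistic_params$t1) {
          # pre-sprouting day: record the bead-only frame all the same
        }
        img <- render_image(net, day = d, bead_id = b)
        handle(img, sprintf("bead%d_day%d", b, d))
      }
    }
  }

  rec <- if (length(records)) do.call(rbind, records) else
    stats::setNames(data.frame(matrix(ncol = length(.record_columns), nrow = 0)),
                    .record_columns)
  ang <- if (length(angles)) do.call(rbind, angles) else NULL

  # per-bead growth fits and velocities
  fits <- list(config_hash = hash, beads = list())
  for (b in unique(rec$bead_id)) {
    rb <- rec[rec$bead_id == b, , drop = FALSE]
    rb <- rb[order(rb$day), , drop = FALSE]
    entry <- list(bead_id = b)
    if (nrow(rb) >= 4 && !all(rb$L_um == rb$L_um[1])) {
      fl <- tryCatch(fit_logistic(time_series(rb$day, rb$L_um, "L", "um")),
                     error = function(e) NULL)
      fa <- tryCatch(fit_logistic(time_series(rb$day, rb$A_um2, "A", "um2")),
                     error = function(e) NULL)
      for (nm in c("L", "A")) {
        f <- if (nm == "L") fl else fa
        if (!is.null(f) && f$converged)
          entry[[paste0("fit_", nm)]] <-
            f[c("Y_max", "k", "t1", "t0", "rate_max", "se_Y_max", "se_k",
                "se_t1", "mape", "wmape")]
      }
      vel <- tryCatch(tip_velocity(time_series(rb$day, rb$L_um),
                                   time_series(rb$day, rb$N_tip),
                                   window_days = cfg$velocity_window_days),
                      error = function(e) NULL)
      if (!is.null(vel)) entry$velocity <- vel
    }
    fits$beads[[as.character(b)]] <- entry
  }
  # pooled segment-length fits by class at the final day of each bead
  last_graphs <- list()
  for (b in unique(rec$bead_id)) {
    rb <- rec[rec$bead_id == b, , drop = FALSE]
    lbl <- sprintf("bead%s_day%s", b, max(rb$day))
    if (lbl %in% names(graphs)) last_graphs[[lbl]] <- graphs[[lbl]]
  }
  for (cls in c("tip", "bifurcating")) {
    lens <- unlist(lapply(last_graphs, segment_lengths_um, class = cls))
    f <- tryCatch(fit_exponential_pdf(lens, bin_width_um = cfg$bin_width_um,
                                      min_length_um = cfg$min_length_um,
                                      population = cls),
                  error = function(e) NULL)
    if (!is.null(f))
      fits[[paste0("length_fit_", cls)]] <-
        f[c("l_star_um", "se_l_star_um", "slope", "intercept", "n",
            "n_bins", "population", "valid")]
  }

  smry <- summarize_records(rec)

  rec_path <- file.path(cfg$out, "records.csv")
  write_records(rec, rec_path)
  ang_path <- file.path(cfg$out, "angles.csv")
  utils::write.csv(ang, ang_path, row.names = FALSE)
  fit_path <- file.path(cfg$out, "fits.json")
  jsonlite::write_json(fits, fit_path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "columns")
  sum_path <- file.path(cfg$out, "summary.csv")
  utils::write.csv(smry, sum_path, row.names = FALSE)
  log_path <- file.path(cfg$out, "run.log")
  writeLines(log_lines, log_path)
  manifest <- list(config_hash = hash,
                   files = basename(c(rec_path, ang_path, fit_path,
                                      sum_path, log_path)))
  jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                       auto_unbox = TRUE)

  invisible(list(records = rec, angles = ang, fits = fits, summary = smry,
                 n_failed = n_failed, out = cfg$out))
}

#' Summarize records by condition and day
#'
#' Mean and standard error of the mean of every metric across beads within
#' each (condition, day) cell; SEM is `NA` for single-bead cells.
#'
#' @param records record data.frame (see [compute_record()]).
#' @param group_by grouping column (default `"condition"`).
#' @return data.frame with one row per (group, day) and `mean_*` / `sem_*`
#'   columns per metric, plus `n_beads`.
#' @export
summarize_records <- function(records, group_by = "condition") {
  if (nrow(records) == 0)
    return(data.frame(condition = character(0), day = integer(0),
                      n_beads = integer(0)))
  metrics <- c("A_um2", "Ac_um2", "L_um", "lambda_um", "rmax_um",
               "N_tip", "N_pb", "G")
  key <- interaction(records[[group_by]], records$day, drop = TRUE)
  rows <- lapply(levels(key), function(lv) {
    sub <- records[key == lv, , drop = FALSE]
    out <- data.frame(condition = sub[[group_by]][1], day = sub$day[1],
                      n_beads = nrow(sub), stringsAsFactors = FALSE)
    for (m in metrics) {
      v <- sub[[m]]
      out[[paste0("mean_", m)]] <- mean(v, na.rm = TRUE)
      out[[paste0("sem_", m)]] <- if (sum(!is.na(v)) > 1)
        stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))) else NA_real_
    }
    out
  })
  out <- do.call(rbind, rows)
  out[order(out$condition, out$day), , drop = FALSE]
}
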