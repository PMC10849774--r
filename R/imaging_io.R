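#' Calibrated single-channel image
#'
#' Container for a 2D fluorescence intensity field together with its physical
#' calibration and acquisition metadata. Pixel (x, y) corresponds to matrix
#' element `pixels[y, x]` (row = y), 1-based.
#'
#' @param pixels numeric matrix of non-negative, finite intensities.
#' @param resolution_um_per_px physical pixel size in micrometres (default
#'   1.25, the calibration of a 10x confocal acquisition).
#' @param bead_id bead label (integer or character), or `NA`.
#' @param day integer acquisition day, or `NA`.
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, resolution_um_per_px = 1.25,
                             bead_id = NA, day = NA) {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("pixels must be a non-empty matrix")
  if (!all(is.finite(pixels)))
    stop("pixel intensities must be finite")
  if (any(pixels < 0))
    stop("pixel intensities must be non-negative")
  if (!is.numeric(resolution_um_per_px) || length(resolution_um_per_px) != 1L ||
      resolution_um_per_px <= 0)
    stop("resolution_um_per_px must be a single positive number")
  structure(
    list(pixels = pixels,
         resolution_um_per_px = as.numeric(resolution_um_per_px),
         bead_id = bead_id, day = day),
    class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image %dx%d px, %.4g um/px, bead=%s, day=%s>\n",
              nrow(x$pixels), ncol(x$pixels), x$resolution_um_per_px,
              as.character(x$bead_id), as.character(x$day)))
  invisible(x)
}

#' Time series of one observable
#'
#' @param day integer-ish vector of acquisition days, strictly increasing.
#' @param value finite numeric values, same length as `day`.
#' @param observable name of the observable (e.g. `"L"`, `"A"`).
#' @param units unit string (e.g. `"um"`).
#' @return `time_series` object (a data.frame with attributes).
#' @export
time_series <- function(day, value, observable = "Y", units = "") {
  if (length(day) == 0L) stop("empty day grid")
  if (length(day) != length(value)) stop("day and value lengths differ")
  if (any(diff(day) <= 0)) stop("days must be strictly increasing")
  if (!all(is.finite(day))) stop("days must be finite")
  ok <- is.finite(value) | is.na(value)
  if (!all(ok)) stop("values must be finite or NA")
  out <- data.frame(day = as.numeric(day), value = as.numeric(value))
  attr(out, "observable") <- observable
  attr(out, "units") <- units
  class(out) <- c("time_series", "data.frame")
  out
}

## ---------------------------------------------------------------------------
## Minimal baseline TIFF (grayscale, uncompressed, single- or multi-page).
## No TIFF reader ships with the supported R stack, so the package carries its
## own: little/big-endian byte order, 8/16-bit, SamplesPerPixel = 1, strip
## layout, IFD chain. Sufficient for the max-projection pipeline and for the
## phantom frames the package writes itself.
## ---------------------------------------------------------------------------

.tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)

.read_uint <- function(raw, off, size, endian) {
  # off is 0-based offset into raw; returns numeric
  b <- as.integer(raw[(off + 1):(off + size)])
  if (endian == "big") b <- rev(b)
  sum(b * 256^(seq_len(size) - 1))
}

.read_tag_values <- function(raw, entry_off, endian) {
  type <- .read_uint(raw, entry_off + 2, 2, endian)
  count <- .read_uint(raw, entry_off + 4, 4, endian)
  size <- .tiff_type_size[as.character(type)]
  if (is.na(size)) return(NULL)
  total <- size * count
  voff <- if (total <= 4) entry_off + 8 else .read_uint(raw, entry_off + 8, 4, endian)
  if (type == 5) {  # RATIONAL
    vapply(seq_len(count) - 1L, function(i) {
      num <- .read_uint(raw, voff + i * 8, 4, endian)
      den <- .read_uint(raw, voff + i * 8 + 4, 4, endian)
      if (den == 0) NA_real_ else num / den
    }, numeric(1))
  } else {
    vapply(seq_len(count) - 1L, function(i)
      .read_uint(raw, voff + i * size, size, endian), numeric(1))
  }
}

#' Read a grayscale TIFF file
#'
#' Baseline TIFF only: uncompressed, single-sample (grayscale), 8- or 16-bit,
#' any number of pages. Returns pixel intensities as stored.
#'
#' @param path file path.
#' @return list of numeric matrices, one per page (row = image row).
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file (too short): ", path)
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    stop("not a TIFF file (bad byte order mark): ", path)
  if (.read_uint(raw, 2, 2, endian) != 42)
    stop("not a TIFF file (bad magic): ", path)
  ifd_off <- .read_uint(raw, 4, 4, endian)
  pages <- list()
  page <- 0L
  while (ifd_off != 0) {
    page <- page + 1L
    n_entries <- .read_uint(raw, ifd_off, 2, endian)
    tags <- list()
    for (i in seq_len(n_entries)) {
      eoff <- ifd_off + 2 + (i - 1) * 12
      tag <- .read_uint(raw, eoff, 2, endian)
      tags[[as.character(tag)]] <- .read_tag_values(raw, eoff, endian)
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    width <- g(256); height <- g(257)
    if (is.null(width) || is.null(height))
      stop(sprintf("TIFF page %d: missing dimensions", page))
    bits <- g(258, 1)
    spp <- g(277, 1)
    if (length(bits) > 1 || spp != 1)
      stop(sprintf("TIFF page %d: multi-channel pages are not supported", page))
    if (g(259, 1) != 1)
      stop(sprintf("TIFF page %d: compressed TIFF is not supported", page))
    if (!bits %in% c(8, 16))
      stop(sprintf("TIFF page %d: unsupported bit depth %d", page, bits))
    offsets <- g(273); counts <- g(279)
    if (is.null(offsets)) stop(sprintf("TIFF page %d: missing strip offsets", page))
    bytes_px <- bits / 8
    vals <- numeric(width * height)
    pos <- 1L
    for (s in seq_along(offsets)) {
      nb <- if (!is.null(counts)) counts[s] else width * height * bytes_px
      npx <- nb / bytes_px
      chunk <- raw[(offsets[s] + 1):(offsets[s] + nb)]
      v <- readBin(chunk, "integer", n = npx, size = bytes_px,
                   signed = FALSE, endian = endian)
      vals[pos:(pos + npx - 1)] <- v
      pos <- pos + npx
    }
    pages[[page]] <- matrix(vals[seq_len(width * height)], nrow = height,
                            ncol = width, byrow = TRUE)
    ifd_off <- .read_uint(raw, ifd_off + 2 + n_entries * 12, 4, endian)
  }
  pages
}

.uint_raw <- function(x, size) {
  # little-endian raw encoding of a non-negative integer value
  writeBin(as.integer(x), raw(), size = size, endian = "little")
}

#' Write a grayscale TIFF file
#'
#' Uncompressed little-endian baseline TIFF, one strip per page.
#'
#' @param pages a numeric matrix or a list of same-shaped numeric matrices.
#' @param path output path.
#' @param bits bit depth, 8 or 16 (default 16). Values are clamped to range
#'   and rounded.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pages, path, bits = 16) {
  if (is.matrix(pages)) pages <- list(pages)
  if (!bits %in% c(8, 16)) stop("bits must be 8 or 16")
  maxv <- 2^bits - 1
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(.uint_raw(42, 2), con)
  # header IFD pointer patched after layout: data blocks first, IFDs after
  n <- length(pages)
  sizes <- vapply(pages, function(m) length(m) * (bits / 8), numeric(1))
  data_off <- numeric(n)
  off <- 8
  for (i in seq_len(n)) { data_off[i] <- off; off <- off + sizes[i] }
  ifd_off <- numeric(n)
  n_tags <- 9L
  ifd_len <- 2 + n_tags * 12 + 4
  for (i in seq_len(n)) { ifd_off[i] <- off; off <- off + ifd_len }
  writeBin(.uint_raw(ifd_off[1], 4), con)
  for (i in seq_len(n)) {
    m <- pages[[i]]
    v <- as.integer(pmax(0, pmin(maxv, round(t(m)))))  # row-major
    writeBin(v, con, size = bits / 8, endian = "little")
  }
  tag_entry <- function(tag, type, count, value) {
    c(.uint_raw(tag, 2), .uint_raw(type, 2), .uint_raw(count, 4),
      .uint_raw(value, 4))
  }
  for (i in seq_len(n)) {
    m <- pages[[i]]
    entries <- c(
      tag_entry(256, 4, 1, ncol(m)),            # ImageWidth
      tag_entry(257, 4, 1, nrow(m)),            # ImageLength
      tag_entry(258, 3, 1, bits),               # BitsPerSample
      tag_entry(259, 3, 1, 1),                  # Compression = none
      tag_entry(262, 3, 1, 1),                  # Photometric = BlackIsZero
      tag_entry(273, 4, 1, data_off[i]),        # StripOffsets
      tag_entry(277, 3, 1, 1),                  # SamplesPerPixel
      tag_entry(278, 4, 1, nrow(m)),            # RowsPerStrip
      tag_entry(279, 4, 1, sizes[i]))           # StripByteCounts
    writeBin(.uint_raw(n_tags, 2), con)
    writeBin(entries, con)
    nxt <- if (i < n) ifd_off[i + 1] else 0
    writeBin(.uint_raw(nxt, 4), con)
  }
  invisible(path)
}

#' Maximum-intensity z-projection
#'
#' Elementwise maximum across a list of equally shaped pages. Projecting a
#' single page (or an already projected image) is the identity.
#'
#' @param pages list of numeric matrices.
#' @return a single numeric matrix.
#' @export
project_max <- function(pages) {
  if (is.matrix(pages)) return(pages)
  if (length(pages) == 0L) stop("no pages to project")
  dims <- vapply(pages, dim, integer(2))
  bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])
  if (length(bad))
    stop(sprintf("non-uniform page shapes: page %d is %dx%d, expected %dx%d",
                 bad[1], dims[1, bad[1]], dims[2, bad[1]], dims[1, 1], dims[2, 1]))
  out <- pages[[1]]
  for (i in seq_along(pages)[-1]) out <- pmax(out, pages[[i]])
  out
}

#' Load a TIFF stack as a calibrated, max-projected image
#'
#' Reads a single-channel TIFF (1..n z-pages), takes the per-pixel maximum
#' across pages, and parses bead/day metadata from the file name.
#'
#' @param path TIFF file path.
#' @param resolution physical pixel size in um/px (default 1.25).
#' @param pattern PCRE with named groups `bead` and `day` applied to the
#'   file name; non-matching names leave the metadata `NA`.
#' @return [calibrated_image()].
#' @export
load_stack <- function(path, resolution = 1.25,
                       pattern = "bead(?P<bead>\\d+)_day(?P<day>\\d+)") {
  pages <- read_tiff(path)
  proj <- project_max(pages)
  fn <- basename(path)
  bead_id <- NA; day <- NA
  m <- regexpr(pattern, fn, perl = TRUE)
  if (m > 0) {
    st <- attr(m, "capture.start"); len <- attr(m, "capture.length")
    nm <- attr(m, "capture.names")
    grab <- function(g) {
      j <- match(g, nm)
      if (is.na(j) || st[j] <= 0) NA else
        as.integer(substr(fn, st[j], st[j] + len[j] - 1))
    }
    bead_id <- grab("bead"); day <- grab("day")
  }
  calibrated_image(proj, resolution_um_per_px = resolution,
                   bead_id = bead_id, day = day)
}

## ---------------------------------------------------------------------------
## Morphometric record CSV round trip
## ---------------------------------------------------------------------------

.record_columns <- c("bead_id", "day", "condition", "A_um2", "Ac_um2", "L_um",
                     "lambda_um", "rmax_um", "N_tip", "N_pb", "G")
.record_numeric <- c("A_um2", "Ac_um2", "L_um", "lambda_um", "rmax_um", "G")
.record_integer <- c("day", "N_tip", "N_pb")

#' Write morphometric records to CSV
#'
#' One row per (bead, day); numeric values are written with 17 significant
#' digits so read-back is lossless. An empty record list produces a
#' header-only file.
#'
#' @param records a data.frame with the record schema (see
#'   [compute_record()]), or a list of single-row record data.frames.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  if (is.data.frame(records)) df <- records
  else if (length(records) == 0L)
    df <- as.data.frame(setNames(rep(list(logical(0)), length(.record_columns)),
                                 .record_columns))
  else df <- do.call(rbind, records)
  missing_cols <- setdiff(.record_columns, names(df))
  if (length(missing_cols))
    stop("records missing columns: ", paste(missing_cols, collapse = ", "))
  df <- df[, .record_columns, drop = FALSE]
  out <- df
  for (cn in .record_numeric)
    out[[cn]] <- vapply(df[[cn]], function(v)
      if (is.na(v)) "" else formatC(v, digits = 17, format = "g"), character(1))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read morphometric records from CSV
#'
#' @param path CSV path written by [write_records()].
#' @return data.frame with the record schema.
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!identical(names(df), .record_columns))
    stop("record schema mismatch: expected columns ",
         paste(.record_columns, collapse = ", "), "; found ",
         paste(names(df), collapse = ", "))
  for (cn in .record_numeric) df[[cn]] <- as.numeric(df[[cn]])
  for (cn in .record_integer) df[[cn]] <- as.integer(df[[cn]])
  if (all(grepl("^-?\\d+$", df$bead_id) | df$bead_id == ""))
    df$bead_id <- as.integer(df$bead_id)
  df
}
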