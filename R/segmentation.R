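## Segmentation of bead-sprouting fluorescence projections:
## blur -> relative-mean threshold -> hole filling -> largest component ->
## bead detection -> bead removal.

#' Pixel-coordinate circle
#'
#' @param center numeric `c(x, y)` in 1-based pixel coordinates.
#' @param radius radius in pixels.
#' @return a `circle_px` list.
#' @export
circle_px <- function(center, radius) {
  stopifnot(length(center) == 2, is.finite(center), is.finite(radius), radius >= 0)
  structure(list(center = as.numeric(center), radius = as.numeric(radius)),
            class = "circle_px")
}

#' Boolean disk mask
#'
#' @param nrow,ncol mask dimensions.
#' @param circle a [circle_px()].
#' @return logical matrix, TRUE within the disk (centre distance <= radius).
#' @export
disk_mask <- function(nrow, ncol, circle) {
  dx <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE) - circle$center[1]
  dy <- matrix(seq_len(nrow), nrow, ncol) - circle$center[2]
  dx * dx + dy * dy <= circle$radius^2
}

.binary_erode <- function(mask, radius) {
  if (radius <= 0) return(mask)
  d2 <- edt_sq_cpp(!mask)          # squared distance to background
  mask & (d2 > radius^2)
}

.binary_dilate <- function(mask, radius) {
  if (radius <= 0 || !any(mask)) return(mask)
  d2 <- edt_sq_cpp(mask)
  d2 <= radius^2
}

#' Threshold segmentation (blur + relative-mean threshold)
#'
#' Gaussian-blurs the image with a `blur_kernel_px` window (sigma =
#' kernel/6), computes the global mean of the blurred image, and marks
#' pixels strictly above `mean * threshold_factor` as foreground. On a
#' constant image this yields an empty foreground; an all-zero image
#' additionally raises a warning.
#'
#' @param img a [calibrated_image()] or a numeric matrix.
#' @param blur_kernel_px Gaussian window size in pixels (default 11).
#' @param threshold_factor multiple of the global mean (default 1.17).
#' @param blur_sigma Gaussian sigma in pixels; default `blur_kernel_px / 6`.
#' @return logical foreground matrix.
#' @export
segment_image <- function(img, blur_kernel_px = 11, threshold_factor = 1.17,
                          blur_sigma = blur_kernel_px / 6) {
  px <- if (inherits(img, "calibrated_image")) img$pixels else img
  if (!is.matrix(px) || length(px) == 0L) stop("non-empty image required")
  if (all(px == 0)) {
    warning("all-zero image: empty foreground")
    return(matrix(FALSE, nrow(px), ncol(px)))
  }
  blurred <- blur_gaussian_cpp(px, as.integer(blur_kernel_px), blur_sigma)
  thr <- mean(blurred) * threshold_factor
  blurred > thr
}

#' Count boundary pixels of a pixel set
#'
#' Number of TRUE pixels having at least one FALSE 8-neighbour inside the
#' image frame. This is the perimeter definition used by [fill_holes()]
#' (holes never touch the frame, so the frame itself is not a boundary).
#'
#' @param mask logical matrix.
#' @return integer count.
#' @export
boundary_pixel_count <- function(mask) {
  if (!any(mask)) return(0L)
  nb <- neighbor_count_cpp(mask)
  # interior pixels of the set have 8 TRUE neighbours; frame pixels can never
  # reach 8, so clip the frame off before comparing
  nr <- nrow(mask); nc <- ncol(mask)
  boundary <- mask & (nb < 8L)
  sum(boundary)
}

#' Fill small holes in a binary mask
#'
#' Background components not connected to the image border whose 8-connected
#' boundary-pixel count is below `max_perimeter_px` are set to foreground;
#' larger holes are left untouched. Idempotent; never removes foreground.
#'
#' @param mask logical matrix.
#' @param max_perimeter_px perimeter threshold in pixels (default 200,
#'   i.e. 250 um at 1.25 um/px).
#' @return logical matrix.
#' @export
fill_holes <- function(mask, max_perimeter_px = 200) {
  bg <- !mask
  if (!any(bg)) return(mask)
  lab <- label_components_cpp(bg, 4L)
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labels <- border_labels[border_labels != 0L]
  hole_labels <- setdiff(unique(lab[lab != 0L]), border_labels)
  out <- mask
  for (h in hole_labels) {
    hole <- lab == h
    if (boundary_pixel_count(hole) < max_perimeter_px) out[hole] <- TRUE
  }
  out
}

#' Keep only the largest connected foreground component
#'
#' 8-connected components; ties broken in favour of the component whose
#' first pixel comes earliest in row-major scan order. An empty mask is
#' returned unchanged.
#'
#' @param mask logical matrix.
#' @return logical matrix.
#' @export
largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- label_components_cpp(mask, 8L)
  sizes <- tabulate(lab[lab != 0L])
  # label order is first-pixel scan order, so which.max resolves ties as stated
  keep <- which.max(sizes)
  lab == keep
}

#' Detect the central bead as a circle
#'
#' Size-selective morphology: a binary opening of the foreground with a disk
#' structuring element removes thin sprouts while preserving the large bead
#' blob; the bead is then the dominant blob of the opening, reported as its
#' centroid and equivalent-area radius.
#'
#' @param img a [calibrated_image()] (supplies the um/px calibration).
#' @param mask logical foreground matrix.
#' @param expected_radius_um expected bead radius (default 132.5 um, a
#'   265 um diameter bead).
#' @param se_factor structuring-element radius as a fraction of the expected
#'   bead radius (default 0.5: large enough to erase sprouts an order of
#'   magnitude thinner than the bead, small enough to keep the bead).
#' @return [circle_px()] with attribute `area_px` (blob pixel count).
#' @export
detect_bead <- function(img, mask, expected_radius_um = 132.5, se_factor = 0.5) {
  if (!any(mask)) stop("bead detection failed: empty mask")
  res <- if (inherits(img, "calibrated_image")) img$resolution_um_per_px else 1.25
  expected_px <- expected_radius_um / res
  r_se <- se_factor * expected_px
  opened <- .binary_dilate(.binary_erode(mask, r_se), r_se)
  min_area <- pi * expected_px^2 / 4
  if (!any(opened))
    stop("bead detection failed: no blob of at least a quarter of the expected bead area")
  lab <- label_components_cpp(opened, 8L)
  sizes <- tabulate(lab[lab != 0L])
  dominant <- which.max(sizes)
  if (sizes[dominant] < min_area)
    stop("bead detection failed: no blob of at least a quarter of the expected bead area")
  idx <- which(lab == dominant, arr.ind = TRUE)
  center <- c(mean(idx[, "col"]), mean(idx[, "row"]))   # (x, y)
  radius <- sqrt(sizes[dominant] / pi)
  out <- circle_px(center, radius)
  attr(out, "area_px") <- sizes[dominant]
  out
}

#' Remove the bead disk from a foreground mask
#'
#' Clears all pixels within `radius + margin_px` of the bead centre. The
#' cleared foreground (foreground intersected with the enlarged disk) is
#' kept as attribute `bead_foreground`; its pixel count supports the
#' cell-on-bead area A_c.
#'
#' @param mask logical foreground matrix.
#' @param bead a [circle_px()].
#' @param margin_px extra clearance beyond the detected radius (default 2).
#' @return logical sprout mask with attribute `bead_foreground`.
#' @export
remove_bead <- function(mask, bead, margin_px = 2) {
  disk <- disk_mask(nrow(mask), ncol(mask),
                    circle_px(bead$center, bead$radius + margin_px))
  sprout <- mask & !disk
  attr(sprout, "bead_foreground") <- mask & disk
  sprout
}

#' Full segmentation recipe
#'
#' blur + threshold, hole filling, largest component, bead detection, bead
#' removal — in the order of the processing workflow. Parameters default to
#' the calibrated recipe for 1.25 um/px acquisitions.
#'
#' @param img a [calibrated_image()].
#' @inheritParams segment_image
#' @inheritParams fill_holes
#' @inheritParams detect_bead
#' @inheritParams remove_bead
#' @return a `segmentation_result`: list with `foreground` (binary grid),
#'   `bead` ([circle_px()]), `sprout_mask`, `bead_foreground`,
#'   `removal_radius_px` (radius + margin actually cleared), `parameters`.
#' @export
segment_bead_image <- function(img, blur_kernel_px = 11, threshold_factor = 1.17,
                               max_perimeter_px = 200,
                               expected_radius_um = 132.5, margin_px = 2) {
  fg <- segment_image(img, blur_kernel_px, threshold_factor)
  fg <- fill_holes(fg, max_perimeter_px)
  fg <- largest_component(fg)
  bead <- detect_bead(img, fg, expected_radius_um)
  sprout <- remove_bead(fg, bead, margin_px)
  structure(
    list(foreground = fg, bead = bead, sprout_mask = sprout,
         bead_foreground = attr(sprout, "bead_foreground"),
         removal_radius_px = bead$radius + margin_px,
         parameters = list(blur_kernel_px = blur_kernel_px,
                           threshold_factor = threshold_factor,
                           hole_perimeter_px = max_perimeter_px,
                           expected_radius_um = expected_radius_um,
                           margin_px = margin_px)),
    class = "segmentation_result")
}
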