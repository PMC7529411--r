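#' Segmented nucleus region
#'
#' One nucleus on one focal plane: a label, the sub-pixel centre, the
#' profiling radius, and the member pixels. The profiling radius is the
#' maximum centroid-to-pixel distance (the centroid-centred circle
#' circumscribing the mask), so the 100% relative radius always reaches the
#' outermost chromatin; see [estimate_center_radius].
#'
#' @param label positive integer nucleus label.
#' @param center numeric `(row, col)` centre, 1-based pixel-centre coordinates.
#' @param radius_px profiling radius in pixels (> 0 for downstream profiling).
#' @param pixels integer vector of linear indices of member pixels.
#' @param dim dimensions `(nrow, ncol)` of the source plane.
#' @param plane_index 1-based index of the focal plane the region was taken
#'   from (1 for single-plane images).
#' @return object of class `nucleus_region`.
#' @export
nucleus_region <- function(label, center, radius_px, pixels, dim,
                           plane_index = 1L) {
  structure(list(label = as.integer(label), center = as.numeric(center),
                 radius_px = as.numeric(radius_px),
                 pixels = as.integer(pixels), dim = as.integer(dim),
                 plane_index = as.integer(plane_index)),
            class = "nucleus_region")
}

#' @export
print.nucleus_region <- function(x, ...) {
  cat(sprintf("<nucleus_region> label %d: center (%.2f, %.2f), radius %.2f px, %d px, plane %d\n",
              x$label, x$center[1], x$center[2], x$radius_px,
              length(x$pixels), x$plane_index))
  invisible(x)
}

#' Segmentation parameters
#'
#' @param sigma Gaussian smoothing standard deviation in pixels applied before
#'   thresholding (0 disables smoothing).
#' @param min_area_px components smaller than this many pixels are discarded.
#' @param exclude_border drop nuclei whose mask touches the image border;
#'   truncated nuclei bias the peripheral intervals of the radial profile.
#' @return named list of parameters.
#' @export
seg_params <- function(sigma = 2, min_area_px = 100, exclude_border = TRUE) {
  if (sigma < 0) stop_field("sigma", "must be >= 0")
  if (min_area_px < 1) stop_field("min_area_px", "must be >= 1")
  list(sigma = sigma, min_area_px = min_area_px,
       exclude_border = isTRUE(exclude_border))
}

#' Segment nuclei in a single plane
#'
#' Deterministic pipeline: Gaussian smoothing (`sigma`) → global Otsu
#' threshold → hole filling → removal of components below `min_area_px` →
#' 8-connected component labelling. Labels are renumbered 1..k in
#' column-major scan order of each component's first pixel. A constant image
#' yields an all-zero mask (no foreground), not an error.
#'
#' @param image [plane_image] or numeric matrix.
#' @param params list from [seg_params].
#' @return integer label matrix (0 = background).
#' @export
segment_nuclei <- function(image, params = seg_params()) {
  px <- as_plane_image(image)$pixels
  rng <- range(px)
  if (rng[1] == rng[2]) {
    return(matrix(0L, nrow(px), ncol(px)))
  }
  norm <- (px - rng[1]) / (rng[2] - rng[1])
  img <- EBImage::Image(norm)
  if (params$sigma > 0) img <- EBImage::gblur(img, sigma = params$sigma)
  thr <- EBImage::otsu(img, range = c(0, 1))
  bw <- EBImage::fillHull(img > thr)
  lbl <- EBImage::imageData(EBImage::bwlabel(bw))
  if (max(lbl) > 0) {
    areas <- tabulate(lbl[lbl > 0])
    keep <- which(areas >= params$min_area_px)
    lbl[!(lbl %in% keep)] <- 0
  }
  relabel_scan_order(lbl)
}

# Renumber positive labels 1..k by first occurrence in column-major order.
relabel_scan_order <- function(lbl) {
  lbl <- as.matrix(lbl)
  pos <- which(lbl > 0)
  out <- matrix(0L, nrow(lbl), ncol(lbl))
  if (length(pos)) {
    old <- lbl[pos]
    first_seen <- unique(old)
    out[pos] <- match(old, first_seen)
  }
  out
}

#' Centre and profiling radius of a pixel mask
#'
#' The centre is the unweighted centroid of the member pixels (robust to the
#' strongly rim-enriched intensities under study, unlike an intensity-weighted
#' centroid); the profiling radius is the maximum Euclidean distance from the
#' centroid to any member pixel, i.e. the smallest centroid-centred circle
#' covering the mask.
#'
#' @param mask logical matrix, or integer vector of linear pixel indices (then
#'   `dim` is required).
#' @param dim matrix dimensions when `mask` is an index vector.
#' @return list with `center` = `(row, col)` and `radius_px`.
#' @export
estimate_center_radius <- function(mask, dim = NULL) {
  if (is.matrix(mask)) {
    idx <- which(mask != 0)
    dims <- base::dim(mask)
  } else {
    if (is.null(dim)) stop_field("dim", "required when mask is an index vector")
    idx <- as.integer(mask)
    dims <- as.integer(dim)
  }
  if (length(idx) == 0L) stop("empty mask: no member pixels", call. = FALSE)
  rows <- ((idx - 1L) %% dims[1]) + 1L
  cols <- ((idx - 1L) %/% dims[1]) + 1L
  center <- c(mean(rows), mean(cols))
  radius <- sqrt(max((rows - center[1])^2 + (cols - center[2])^2))
  list(center = center, radius_px = radius)
}

#' Extract nucleus regions from a label mask
#'
#' Converts a labelled mask (from [segment_nuclei] or a user-supplied mask via
#' [read_label_mask]) into [nucleus_region]s with centroid and profiling
#' radius. Regions touching the image border are dropped when
#' `exclude_border` is `TRUE`; single-pixel regions (radius 0) are always
#' dropped since they cannot be profiled.
#'
#' @param mask integer label matrix (0 = background).
#' @param exclude_border drop regions touching the image border.
#' @param plane_index plane index recorded on each region.
#' @return list of [nucleus_region] objects, ordered by label.
#' @export
nucleus_regions <- function(mask, exclude_border = TRUE, plane_index = 1L) {
  mask <- as.matrix(mask)
  labs <- sort(unique(mask[mask > 0]))
  out <- list()
  for (lab in labs) {
    idx <- which(mask == lab)
    rows <- ((idx - 1L) %% nrow(mask)) + 1L
    cols <- ((idx - 1L) %/% nrow(mask)) + 1L
    if (exclude_border &&
        (min(rows) == 1L || max(rows) == nrow(mask) ||
         min(cols) == 1L || max(cols) == ncol(mask))) next
    est <- estimate_center_radius(idx, dim = dim(mask))
    if (est$radius_px <= 0) next
    out[[length(out) + 1L]] <- nucleus_region(
      label = lab, center = est$center, radius_px = est$radius_px,
      pixels = idx, dim = dim(mask), plane_index = plane_index)
  }
  out
}

#' Select the equatorial focal plane of a z-stack
#'
#' The equatorial plane is the optical section through a nucleus's widest
#' cross-section. Each plane is segmented with [segment_nuclei]; the plane
#' with the largest total segmented nucleus area is returned (1-based index),
#' ties broken toward the lower index — for a sphere imaged with an odd number
#' of symmetric sections this is the true midplane.
#'
#' @param stack [image_stack] (a [plane_image] counts as a 1-plane stack).
#' @param params segmentation parameters ([seg_params]).
#' @return 1-based plane index.
#' @export
select_equatorial_plane <- function(stack, params = seg_params()) {
  if (inherits(stack, "plane_image")) return(1L)
  if (!inherits(stack, "image_stack")) stop_field("stack", "must be an image_stack")
  areas <- vapply(stack$planes, function(p) {
    sum(segment_nuclei(p, params) > 0)
  }, numeric(1))
  if (all(areas == 0)) {
    stop("no plane in the stack segments any nucleus", call. = FALSE)
  }
  which.max(areas)
}

#' Sphere volume from diameter
#'
#' Volume of a sphere of diameter `d`: \eqn{(\pi/6) d^3}. Used to convert
#' measured nuclear diameters (micrometres) into nuclear volumes (cubic
#' micrometres) when relating polyteny level to nuclear size.
#'
#' @param d diameter in micrometres (vectorised, all > 0).
#' @return volume in cubic micrometres.
#' @examples
#' round(sphere_volume_from_diameter(c(26.8, 11.1)))
#' @export
sphere_volume_from_diameter <- function(d) {
  if (!is.numeric(d) || any(!is.finite(d)) || any(d <= 0)) {
    stop_field("d", "diameter must be positive and finite")
  }
  (pi / 6) * d^3
}
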