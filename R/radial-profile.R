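#' Concentric-ring integrated intensity profile
#'
#' The intensity at a given distance from the nucleus centre is the sum of the
#' pixel values around a circle at that distance. Every pixel whose centre
#' lies within `radius_px` of the region centre is assigned to exactly one
#' integer ring by rounding its distance (half up), clamped to
#' `floor(radius_px)`, so the rings partition the disk exactly and the ring
#' sums conserve the total in-circle intensity.
#'
#' @param image [plane_image] or numeric matrix.
#' @param region [nucleus_region] providing centre and profiling radius.
#' @param border one of `"error"` (default: the profiling circle must fit
#'   inside the image) or `"clip"` (out-of-image pixels are ignored and the
#'   profile flagged `clipped`).
#' @return data.frame of class `raw_radial_profile` with columns
#'   `ring_radius` (0..floor(radius_px)), `ring_sum`, `ring_count`, and
#'   attributes `radius_px` and `clipped`.
#' @export
compute_raw_profile <- function(image, region, border = c("error", "clip")) {
  border <- match.arg(border)
  px <- as_plane_image(image)$pixels
  ctr <- region$center
  R <- region$radius_px
  if (!is.numeric(R) || R <= 0) stop_field("radius_px", "must be > 0")
  clipped <- FALSE
  lo_r <- ctr[1] - R; hi_r <- ctr[1] + R
  lo_c <- ctr[2] - R; hi_c <- ctr[2] + R
  if (lo_r < 1 || lo_c < 1 || hi_r > nrow(px) || hi_c > ncol(px)) {
    if (border == "error") {
      stop(sprintf(
        "profiling circle (center %.1f,%.1f radius %.1f) exceeds the %d x %d image",
        ctr[1], ctr[2], R, nrow(px), ncol(px)), call. = FALSE)
    }
    clipped <- TRUE
  }
  rows <- max(1L, floor(lo_r)):min(nrow(px), ceiling(hi_r))
  cols <- max(1L, floor(lo_c)):min(ncol(px), ceiling(hi_c))
  dr <- rows - ctr[1]
  dc <- cols - ctr[2]
  d2 <- outer(dr^2, dc^2, "+")
  sel <- d2 <= R^2
  d <- sqrt(d2[sel])
  vals <- px[rows, cols, drop = FALSE][sel]
  nring <- floor(R)
  ring <- pmin(floor(d + 0.5), nring)  # round half up, outermost ring absorbs the remainder
  ring_sum <- numeric(nring + 1L)
  ring_count <- integer(nring + 1L)
  agg_s <- rowsum(vals, ring)
  agg_n <- rowsum(rep(1L, length(ring)), ring)
  at <- as.integer(rownames(agg_s)) + 1L
  ring_sum[at] <- agg_s[, 1]
  ring_count[at] <- agg_n[, 1]
  structure(
    data.frame(ring_radius = 0:nring, ring_sum = ring_sum,
               ring_count = ring_count),
    radius_px = R, clipped = clipped,
    class = c("raw_radial_profile", "data.frame"))
}

#' Normalise a raw radial profile
#'
#' Converts ring radii to relative coordinates (percent of the profiling
#' radius, 0–100%) and divides the profiled quantity by its maximum over the
#' nucleus, so values lie in \[0,1\] with maximum exactly 1. The profiled
#' quantity is the ring sum by default; `ring_statistic = "mean"` divides each
#' ring sum by its pixel count first (the convention of count-normalising
#' radial profile tools), changing the shape weighting but not the downstream
#' machinery.
#'
#' @param raw `raw_radial_profile` from [compute_raw_profile].
#' @param ring_statistic `"sum"` or `"mean"`.
#' @return data.frame of class `normalized_profile` with columns `rel_radius`
#'   (percent, strictly increasing) and `rel_intensity` in \[0,1\].
#' @export
normalize_profile <- function(raw, ring_statistic = c("sum", "mean")) {
  ring_statistic <- match.arg(ring_statistic)
  R <- attr(raw, "radius_px")
  v <- raw$ring_sum
  if (ring_statistic == "mean") {
    v <- ifelse(raw$ring_count > 0, v / raw$ring_count, 0)
  }
  if (all(v <= 0)) stop("empty nucleus: all ring intensities are zero", call. = FALSE)
  structure(
    data.frame(rel_radius = 100 * raw$ring_radius / R,
               rel_intensity = v / max(v)),
    class = c("normalized_profile", "data.frame"))
}

#' Bin a normalised profile into 5% intervals
#'
#' The 0–100% relative axis is divided into twenty half-open intervals
#' `(x-5, x]` labelled by their right edge `x` in 5, 10, ..., 100; relative
#' radius 0 is folded into the first interval. The per-nucleus value of an
#' interval is the mean of the ring values falling in it; intervals receiving
#' no ring are `NA` (missing, never imputed as zero).
#'
#' @param profile `normalized_profile` from [normalize_profile].
#' @param bin_width interval width in percent; must divide 100 (default 5).
#' @return data.frame of class `binned_profile` with columns `x` and `value`.
#' @export
bin_profile <- function(profile, bin_width = 5) {
  if (100 %% bin_width != 0) stop_field("bin_width", "must divide 100")
  edges <- seq(bin_width, 100, by = bin_width)
  idx <- pmax(ceiling(profile$rel_radius / bin_width), 1L)
  vals <- rep(NA_real_, length(edges))
  agg <- rowsum(profile$rel_intensity, idx)
  cnt <- rowsum(rep(1L, length(idx)), idx)
  at <- as.integer(rownames(agg))
  vals[at] <- agg[, 1] / cnt[, 1]
  structure(data.frame(x = edges, value = vals),
            class = c("binned_profile", "data.frame"))
}

#' Measure every nucleus on a plane
#'
#' Convenience wrapper running [compute_raw_profile], [normalize_profile] and
#' [bin_profile] for a list of regions and assembling tidy [profile_table]
#' rows.
#'
#' @param image [plane_image] or matrix.
#' @param regions list of [nucleus_region].
#' @param image_id identifier recorded in the table.
#' @param group group label recorded in the table.
#' @param ring_statistic passed to [normalize_profile].
#' @param bin_width passed to [bin_profile].
#' @param border passed to [compute_raw_profile].
#' @return [profile_table] data.frame (one row per nucleus and interval).
#' @export
measure_plane <- function(image, regions, image_id, group = "reference",
                          ring_statistic = "sum", bin_width = 5,
                          border = "error") {
  rows <- lapply(regions, function(reg) {
    raw <- compute_raw_profile(image, reg, border = border)
    binned <- bin_profile(normalize_profile(raw, ring_statistic), bin_width)
    data.frame(image_id = image_id, nucleus = reg$label, group = group,
               x = binned$x, value = binned$value, stringsAsFactors = FALSE)
  })
  profile_table(do.call(rbind, rows))
}
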