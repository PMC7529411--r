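#' Image containers
#'
#' A `plane_image` is a single-channel 2D intensity raster (numeric matrix,
#' rows = image rows) with optional physical pixel size; an `image_stack` is an
#' ordered list of equally sized planes with optional z spacing. Pixel
#' coordinates throughout the package are 1-based with the origin at the
#' centre of the top-left pixel, matching R matrix indexing.
#'
#' @param pixels numeric matrix of finite, nonnegative intensities.
#' @param pixel_size_um physical edge length of one pixel in micrometres, or
#'   `NULL` if unknown.
#' @return `plane_image()` returns an object of class `plane_image` with
#'   elements `pixels` and `pixel_size_um`.
#' @export
plane_image <- function(pixels, pixel_size_um = NULL) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (!all(is.finite(pixels))) stop_field("pixels", "intensities must be finite")
  if (any(pixels < 0)) stop_field("pixels", "intensities must be >= 0")
  if (!is.null(pixel_size_um) && (!is.numeric(pixel_size_um) || pixel_size_um <= 0)) {
    stop_field("pixel_size_um", "must be a positive length")
  }
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um),
            class = "plane_image")
}

#' @rdname plane_image
#' @param planes list of `plane_image` objects (or matrices) sharing dimensions.
#' @param z_step_um spacing between consecutive planes in micrometres, or `NULL`.
#' @export
image_stack <- function(planes, pixel_size_um = NULL, z_step_um = NULL) {
  planes <- lapply(planes, function(p) {
    if (inherits(p, "plane_image")) p else plane_image(p, pixel_size_um)
  })
  if (length(planes) == 0L) stop_field("planes", "stack must be nonempty")
  dims <- vapply(planes, function(p) dim(p$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_field("planes", "all planes must share dimensions")
  }
  structure(list(planes = planes, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um),
            class = "image_stack")
}

as_plane_image <- function(x, pixel_size_um = NULL) {
  if (inherits(x, "plane_image")) x else plane_image(x, pixel_size_um)
}

#' @export
print.plane_image <- function(x, ...) {
  cat(sprintf("<plane_image> %d x %d px%s, range [%g, %g]\n",
              nrow(x$pixels), ncol(x$pixels),
              if (is.null(x$pixel_size_um)) "" else
                sprintf(" (%g um/px)", x$pixel_size_um),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %d planes of %d x %d px\n", length(x$planes),
              nrow(x$planes[[1]]$pixels), ncol(x$planes[[1]]$pixels)))
  invisible(x)
}

# tiff::readTIFF returns matrices in image orientation row = scanline, which
# matches our row convention; RGB pages come back with a 3rd dimension.
read_tiff_pages <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  pages <- tryCatch({
    meta <- tiff::readTIFF(path, payload = FALSE)
    # integer samples are read as stored; 32-bit (float) samples natively
    is_float <- any(meta$bits.per.sample >= 32)
    tiff::readTIFF(path, all = TRUE, as.is = !is_float)
  }, error = function(e) {
    stop(sprintf("cannot read TIFF '%s': %s", path,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (length(dim(p)) == 3L) {
      stop(sprintf(
        "'%s' has %d channels; supply a single-channel (grayscale) image",
        path, dim(p)[3]), call. = FALSE)
    }
  }
  pages
}

#' Read a TIFF image or stack
#'
#' Single-page grayscale TIFFs become a [plane_image]; multi-page TIFFs become
#' an [image_stack] preserving page order. Integer (8/16-bit) and 32-bit float
#' sample formats are accepted; integer data are read as stored (no rescaling
#' to \[0,1\]). RGB input is rejected.
#'
#' @param path path to a TIFF file.
#' @param pixel_size_um,z_step_um optional physical calibration to attach.
#' @return [plane_image] or [image_stack].
#' @export
read_image <- function(path, pixel_size_um = NULL, z_step_um = NULL) {
  pages <- read_tiff_pages(path)
  if (length(pages) == 1L) {
    plane_image(pages[[1]], pixel_size_um)
  } else {
    image_stack(pages, pixel_size_um = pixel_size_um, z_step_um = z_step_um)
  }
}

#' Write a plane image or stack as TIFF
#'
#' Integer-valued data within 16-bit range are written as 16-bit unsigned
#' integers (lossless round trip with [read_image]); anything else is written
#' as 32-bit float.
#'
#' @param image [plane_image], [image_stack], or numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  mats <- if (inherits(image, "image_stack")) {
    lapply(image$planes, function(p) p$pixels)
  } else {
    list(as_plane_image(image)$pixels)
  }
  all_int <- all(vapply(mats, function(m) {
    all(m == round(m)) && max(m) <= 65535
  }, logical(1)))
  out <- if (all_int) {
    lapply(mats, function(m) m / 65535)
  } else {
    mats
  }
  bits <- if (all_int) 16L else 32L
  if (length(out) == 1L) out <- out[[1]]
  tiff::writeTIFF(out, path, bits.per.sample = bits)
  invisible(path)
}

#' Read or write an integer label mask
#'
#' Label masks are single-plane TIFFs with unsigned-integer samples; 0 marks
#' background and each positive label one nucleus. Floating-point sample
#' formats are rejected to avoid silently truncated labels.
#'
#' @param path path to a TIFF file.
#' @return `read_label_mask()` returns an integer matrix.
#' @export
read_label_mask <- function(path) {
  meta <- tryCatch(tiff::readTIFF(path, payload = FALSE),
                   error = function(e) {
                     stop(sprintf("cannot read TIFF '%s': %s", path,
                                  conditionMessage(e)), call. = FALSE)
                   })
  fmt <- if (!is.null(meta$sample.format)) meta$sample.format else
    ifelse(meta$bits.per.sample >= 32, "float", "uint")
  if (any(fmt != "uint")) {
    stop(sprintf("label mask '%s' has a floating-point sample format; integer required",
                 path), call. = FALSE)
  }
  pages <- read_tiff_pages(path)
  if (length(pages) > 1L) {
    stop(sprintf("label mask '%s' has %d pages; a single plane is required",
                 path, length(pages)), call. = FALSE)
  }
  m <- pages[[1]]
  if (any(m != round(m))) {
    stop(sprintf("label mask '%s' contains non-integer values", path),
         call. = FALSE)
  }
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_label_mask
#' @param mask integer matrix of labels (0 = background).
#' @export
write_label_mask <- function(mask, path) {
  mask <- as.matrix(mask)
  if (any(mask != round(mask)) || any(mask < 0)) {
    stop_field("mask", "labels must be nonnegative integers")
  }
  if (max(mask) > 65535) stop_field("mask", "labels exceed 16-bit range")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

## ---- tidy tables -----------------------------------------------------------

profile_table_schema <- c("image_id", "nucleus", "group", "x", "value")

#' Per-nucleus binned profile table
#'
#' The tidy interchange table for binned profiles: one row per nucleus and 5%
#' interval, columns `image_id`, `nucleus`, `group`, `x` (right edge of the
#' interval, a multiple of 5 in 5..100) and `value` (the per-nucleus relative
#' intensity in \[0,1\], `NA` for an interval no ring fell into).
#'
#' @param df data.frame with the columns above.
#' @return validated data.frame (class `profile_table`).
#' @export
profile_table <- function(df) {
  check_schema(df, profile_table_schema, "profile table")
  df$x <- as.numeric(df$x)
  bad <- df$x %% 5 != 0 | df$x < 5 | df$x > 100
  if (any(bad)) {
    stop_field("x", "interval positions must be multiples of 5 in [5, 100]")
  }
  ok <- is.na(df$value) | (df$value >= 0 & df$value <= 1)
  if (!all(ok)) stop_field("value", "values must be in [0, 1] or NA")
  key <- paste(df$image_id, df$nucleus, df$x)
  if (anyDuplicated(key)) {
    stop_field("x", "each (image, nucleus) may contribute at most one value per interval")
  }
  class(df) <- c("profile_table", "data.frame")
  df
}

check_schema <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Read and write tidy CSV tables
#'
#' All numeric columns are serialised at full double precision (15 significant
#' digits), so write/read is lossless for the package's tables. `read_csv_table`
#' validates that `required` columns are present and errors naming any that are
#' missing.
#'
#' @param df data.frame to write.
#' @param path CSV path.
#' @param required character vector of required column names.
#' @return `read_csv_table()` returns a data.frame.
#' @export
write_csv_table <- function(df, path) {
  df <- as.data.frame(df)
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      df[[nm]] <- vapply(df[[nm]], function(v) {
        if (is.na(v)) NA_character_ else format(v, digits = 15, scientific = FALSE)
      }, character(1))
    }
  }
  write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_csv_table
#' @export
read_csv_table <- function(path, required = character()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (length(required)) check_schema(df, required, basename(path))
  df
}

#' @rdname profile_table
#' @param path CSV path.
#' @export
write_profile_table <- function(df, path) {
  write_csv_table(as.data.frame(profile_table(as.data.frame(df))), path)
}

#' @rdname profile_table
#' @export
read_profile_table <- function(path) {
  df <- read_csv_table(path, required = profile_table_schema)
  profile_table(df)
}

#' Read and write run configuration
#'
#' Configurations are plain named lists stored as JSON (`.json`) or YAML
#' (`.yml`/`.yaml`), chosen by file extension.
#'
#' @param config named list.
#' @param path destination with `.json`, `.yml` or `.yaml` extension.
#' @return `read_config()` returns a named list.
#' @export
write_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    yaml::write_yaml(config, path)
  } else {
    stop(sprintf("unsupported config extension '.%s' (use json/yml/yaml)", ext),
         call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    stop(sprintf("unsupported config extension '.%s' (use json/yml/yaml)", ext),
         call. = FALSE)
  }
}
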