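#' Radial intensity laws
#'
#' A radial law describes the expected chromatin (DAPI) intensity as a
#' function of relative radius \eqn{\rho \in [0,1]} inside a nucleus, with
#' \eqn{\rho = 0} at the centre and \eqn{\rho = 1} at the profiling radius.
#' Four kinds are supported:
#' \describe{
#'   \item{`uniform`}{constant intensity 1 plus `base_level`.}
#'   \item{`peripheral_rim`}{a unit-peak Gaussian ring
#'     \eqn{\exp(-(\rho - c)^2 / 2\sigma^2)} centred at `rim_center`,
#'     emulating lamina-tethered chromatin at the nuclear periphery.}
#'   \item{`central_blob`}{a unit-peak Gaussian \eqn{\exp(-\rho^2/2 b^2)} at
#'     the centre, emulating centrally relocated chromatin.}
#'   \item{`mixture`}{`(1 - mix_weight) * rim + mix_weight * blob`.}
#' }
#' `base_level` is added to every kind. Laws are specified on relative radius
#' so one law serves nuclei of any physical size.
#'
#' @param kind one of `"uniform"`, `"peripheral_rim"`, `"central_blob"`,
#'   `"mixture"`.
#' @param rim_center peak position of the rim component, relative radius in
#'   \[0,1\].
#' @param rim_width Gaussian standard deviation of the rim, relative-radius
#'   units, > 0.
#' @param blob_width Gaussian standard deviation of the central component, > 0.
#' @param mix_weight fraction in \[0,1\] of the mixture assigned to the
#'   central component.
#' @param base_level nonnegative background added everywhere inside the
#'   nucleus, in units of the unit-peak components.
#' @return `radial_law_spec()` returns a validated spec (class
#'   `radial_law_spec`); `radial_law()` returns a vectorised function
#'   \eqn{f(\rho)}, deterministic and nonnegative on \[0,1\].
#' @examples
#' f <- radial_law(radial_law_spec("peripheral_rim", rim_center = 0.85))
#' f(c(0, 0.85, 1))
#' @export
radial_law_spec <- function(kind = c("peripheral_rim", "uniform",
                                     "central_blob", "mixture"),
                            rim_center = 0.85, rim_width = 0.08,
                            blob_width = 0.25, mix_weight = 0,
                            base_level = 0.1) {
  kind <- match.arg(kind)
  num1 <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop_field(field, "must be a single finite number")
    }
    x
  }
  rim_center <- num1(rim_center, "rim_center")
  if (rim_center < 0 || rim_center > 1) stop_field("rim_center", "must lie in [0, 1]")
  rim_width <- num1(rim_width, "rim_width")
  if (rim_width <= 0) stop_field("rim_width", "must be > 0")
  blob_width <- num1(blob_width, "blob_width")
  if (blob_width <= 0) stop_field("blob_width", "must be > 0")
  mix_weight <- num1(mix_weight, "mix_weight")
  if (mix_weight < 0 || mix_weight > 1) stop_field("mix_weight", "must lie in [0, 1]")
  base_level <- num1(base_level, "base_level")
  if (base_level < 0) stop_field("base_level", "must be >= 0")
  structure(list(kind = kind, rim_center = rim_center, rim_width = rim_width,
                 blob_width = blob_width, mix_weight = mix_weight,
                 base_level = base_level),
            class = "radial_law_spec")
}

#' @rdname radial_law_spec
#' @param spec a `radial_law_spec`.
#' @export
radial_law <- function(spec) {
  if (!inherits(spec, "radial_law_spec")) spec <- do.call(radial_law_spec, spec)
  rim <- function(rho) exp(-(rho - spec$rim_center)^2 / (2 * spec$rim_width^2))
  blob <- function(rho) exp(-rho^2 / (2 * spec$blob_width^2))
  base <- spec$base_level
  switch(spec$kind,
    uniform        = function(rho) rep.int(1, length(rho)) + base,
    peripheral_rim = function(rho) rim(rho) + base,
    central_blob   = function(rho) blob(rho) + base,
    mixture        = function(rho) {
      (1 - spec$mix_weight) * rim(rho) + spec$mix_weight * blob(rho) + base
    }
  )
}

# 2D mass of a law over the unit disk, up to the constant 2*pi:
# integral of f(rho) * rho d rho on [0, 1].
law_disk_mass <- function(f) {
  integrate(function(r) f(r) * r, 0, 1, rel.tol = 1e-9)$value
}

law_max <- function(f) max(f(seq(0, 1, length.out = 2001)))

#' Shift intensity mass from the rim to the centre
#'
#' Builds the "test group" law of a two-group simulation: a fraction
#' `shift_fraction` of the 2D intensity mass carried by the peripheral rim
#' component is reassigned to the central blob component, leaving the
#' background untouched. With `shift_fraction = 0` the law is returned
#' unchanged, so the two groups of a cohort are then drawn from identical
#' distributions.
#'
#' @param spec a [radial_law_spec] whose kind involves a rim
#'   (`peripheral_rim` or `mixture`).
#' @param shift_fraction fraction in \[0,1\] of the rim's intensity mass to
#'   move to the central component.
#' @return a `radial_law_spec` of kind `mixture`.
#' @export
shift_law <- function(spec, shift_fraction) {
  if (!inherits(spec, "radial_law_spec")) spec <- do.call(radial_law_spec, spec)
  if (!is.numeric(shift_fraction) || length(shift_fraction) != 1L ||
      shift_fraction < 0 || shift_fraction > 1) {
    stop_field("shift_fraction", "must lie in [0, 1]")
  }
  if (!spec$kind %in% c("peripheral_rim", "mixture")) {
    stop_field("kind", "shift_law needs a law with a rim component")
  }
  if (shift_fraction == 0) return(spec)
  w0 <- if (spec$kind == "mixture") spec$mix_weight else 0
  # Unit-peak component masses on the disk; amplitudes are reweighted in mass
  # units so the rim loses exactly `shift_fraction` of its mass to the blob.
  m_rim <- law_disk_mass(function(r) exp(-(r - spec$rim_center)^2 / (2 * spec$rim_width^2)))
  m_blob <- law_disk_mass(function(r) exp(-r^2 / (2 * spec$blob_width^2)))
  a_rim <- (1 - w0) * (1 - shift_fraction)
  a_blob <- w0 + (1 - w0) * shift_fraction * m_rim / m_blob
  radial_law_spec("mixture", rim_center = spec$rim_center,
                  rim_width = spec$rim_width, blob_width = spec$blob_width,
                  mix_weight = a_blob / (a_rim + a_blob),
                  base_level = spec$base_level)
}

#' Rendering parameters for one synthetic nucleus
#'
#' @param diameter_um nucleus diameter (major axis) in micrometres.
#' @param pixel_size_um pixel edge length in micrometres.
#' @param eccentricity ellipse eccentricity in \[0,1); 0 renders a circle.
#' @param orientation major-axis angle in radians.
#' @param peak_intensity expected photon count at the profile maximum.
#' @param noise `"none"`, `"poisson"`, or `"gaussian"`.
#' @param gaussian_sd standard deviation of additive Gaussian noise (counts),
#'   used when `noise = "gaussian"`.
#' @param seed integer seed for the noise draw, or `NULL`. With
#'   `noise = "none"` the seed has no effect on the rendered image.
#' @param canvas_px optional canvas side length in pixels; the default fits
#'   the nucleus with an 8-pixel margin. An explicit canvas too small for the
#'   nucleus is an error.
#' @return a validated spec of class `nucleus_render_spec`.
#' @export
nucleus_render_spec <- function(diameter_um = 11.1, pixel_size_um = 0.2,
                                eccentricity = 0, orientation = 0,
                                peak_intensity = 1000,
                                noise = c("poisson", "none", "gaussian"),
                                gaussian_sd = 10, seed = NULL,
                                canvas_px = NULL) {
  noise <- match.arg(noise)
  if (!is.numeric(diameter_um) || diameter_um <= 0) {
    stop_field("diameter_um", "must be > 0")
  }
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop_field("pixel_size_um", "must be > 0")
  }
  if (eccentricity < 0 || eccentricity >= 1) {
    stop_field("eccentricity", "must lie in [0, 1)")
  }
  if (peak_intensity <= 0) stop_field("peak_intensity", "must be > 0")
  if (gaussian_sd < 0) stop_field("gaussian_sd", "must be >= 0")
  a_px <- diameter_um / (2 * pixel_size_um)
  if (a_px < 3) {
    stop_field("diameter_um", "rendered radius must be at least 3 pixels")
  }
  structure(list(diameter_um = diameter_um, pixel_size_um = pixel_size_um,
                 eccentricity = eccentricity, orientation = orientation,
                 peak_intensity = peak_intensity, noise = noise,
                 gaussian_sd = gaussian_sd, seed = seed,
                 canvas_px = canvas_px),
            class = "nucleus_render_spec")
}

#' Render a synthetic nucleus image
#'
#' Renders an elliptical nucleus whose expected pixel value at elliptical
#' relative radius \eqn{\rho} is `peak_intensity * f(rho) / max f`; pixels
#' outside the ellipse are zero background. With `noise = "none"` the image
#' equals the expectation exactly; `"poisson"` draws per-pixel photon counts,
#' `"gaussian"` adds zero-mean read noise (clamped at zero).
#'
#' @param law a function \eqn{f(\rho)} from [radial_law], or a
#'   [radial_law_spec].
#' @param render a [nucleus_render_spec].
#' @return a list with `image` ([plane_image]) and `region` (the ground-truth
#'   [nucleus_region]: true centre, profiling radius = major semi-axis, and
#'   in-ellipse pixel mask).
#' @export
render_nucleus <- function(law, render = nucleus_render_spec()) {
  if (inherits(law, "radial_law_spec") || (is.list(law) && !is.function(law))) {
    law <- radial_law(law)
  }
  stopifnot(is.function(law))
  a <- render$diameter_um / (2 * render$pixel_size_um)
  b <- a * sqrt(1 - render$eccentricity^2)
  n <- if (is.null(render$canvas_px)) 2L * ceiling(a) + 17L else as.integer(render$canvas_px)
  if (n < 2 * a + 1) {
    stop(sprintf("nucleus (major axis %.1f px) does not fit a %d px canvas",
                 2 * a, n), call. = FALSE)
  }
  cr <- (n + 1) / 2
  cc <- (n + 1) / 2
  dx <- matrix(rep(seq_len(n) - cc, each = n), n, n)   # column offsets
  dy <- matrix(rep(seq_len(n) - cr, times = n), n, n)  # row offsets
  th <- render$orientation
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  rho <- sqrt((u / a)^2 + (v / b)^2)
  inside <- rho <= 1
  fmax <- law_max(law)
  expected <- matrix(0, n, n)
  expected[inside] <- render$peak_intensity * law(rho[inside]) / fmax
  img <- switch(render$noise,
    none = expected,
    poisson = with_seed(render$seed, {
      out <- expected
      out[inside] <- rpois(sum(inside), expected[inside])
      out
    }),
    gaussian = with_seed(render$seed, {
      out <- expected + rnorm(length(expected), sd = render$gaussian_sd)
      pmax(out, 0)
    })
  )
  region <- nucleus_region(label = 1L, center = c(cr, cc), radius_px = a,
                           pixels = which(inside), dim = c(n, n),
                           plane_index = 1L)
  list(image = plane_image(img, render$pixel_size_um), region = region)
}

#' Two-group cohort specification
#'
#' Describes a simulated two-group experiment: a reference group rendered from
#' `law`, and a test group rendered from [shift_law]`(law, shift_fraction)`.
#' `size_class` sets the mean nucleus diameter to the two polytene size
#' classes under study: `"salivary_like"` (26.8 um) or `"proventriculus_like"`
#' (11.1 um). Per-nucleus diameters vary with 8% coefficient of variation;
#' eccentricity is uniform on \[0, 0.3\] and orientation uniform on \[0, pi).
#'
#' @param n_per_group nuclei per group (>= 2); the study imaged roughly 80–100
#'   nuclei per group, the default is 90.
#' @param shift_fraction fraction of rim intensity mass moved to the centre in
#'   the test group (0 = null cohort: both groups identical).
#' @param size_class `"proventriculus_like"` or `"salivary_like"`.
#' @param law reference-group [radial_law_spec].
#' @param base_render [nucleus_render_spec] providing pixel size, peak
#'   intensity and noise model; per-nucleus geometry and seeds are drawn on
#'   top of it.
#' @param seed integer master seed; all randomness (geometry and per-nucleus
#'   noise seeds) derives from it.
#' @return validated spec of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 90, shift_fraction = 0,
                        size_class = c("proventriculus_like", "salivary_like"),
                        law = radial_law_spec(),
                        base_render = nucleus_render_spec(),
                        seed = 1L) {
  size_class <- match.arg(size_class)
  if (!is.numeric(n_per_group) || n_per_group < 2) {
    stop_field("n_per_group", "must be >= 2")
  }
  if (shift_fraction < 0 || shift_fraction > 1) {
    stop_field("shift_fraction", "must lie in [0, 1]")
  }
  if (!inherits(law, "radial_law_spec")) law <- do.call(radial_law_spec, law)
  structure(list(n_per_group = as.integer(n_per_group),
                 shift_fraction = shift_fraction, size_class = size_class,
                 law = law, base_render = base_render,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

size_class_diameter <- function(size_class) {
  switch(size_class, salivary_like = 26.8, proventriculus_like = 11.1)
}

# Peak rescaling that keeps total rendered nucleus intensity equal between the
# reference law and a shifted law: rendering scales by peak / max f, so the
# total is peak * mass(f) / max(f); the shift must relocate mass, not add it.
conserving_peak <- function(peak, f_ref, f_test) {
  peak * (law_max(f_test) / law_max(f_ref)) *
    (law_disk_mass(f_ref) / law_disk_mass(f_test))
}

#' Simulate a two-group cohort of nucleus images
#'
#' Renders `2 * n_per_group` nuclei: the reference group from `spec$law`, the
#' test group from the shifted law. The test group's peak intensity is
#' rescaled so a shifted nucleus carries the same expected total intensity as
#' an unshifted one — the shift relocates chromatin, it does not add DNA.
#' All geometry and noise derive deterministically from `spec$seed` via
#' per-nucleus child seeds, so identical specs give identical cohorts.
#'
#' @param spec a [cohort_spec].
#' @param dir optional directory; when given, one 16-bit TIFF per nucleus plus
#'   `manifest.csv` and the resolved spec (`cohort-spec.json`) are written.
#' @return a list of class `cohort` with `images` (named list of
#'   [plane_image]), `regions` (ground-truth [nucleus_region]s), `manifest`
#'   (data.frame: image_id, group, file, seed, diameter_um, eccentricity,
#'   orientation, pixel_size_um, peak_intensity, center_row, center_col,
#'   radius_px) and `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), dir = NULL) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  n <- spec$n_per_group
  f_ref <- radial_law(spec$law)
  test_spec <- shift_law(spec$law, spec$shift_fraction)
  f_test <- radial_law(test_spec)
  mean_d <- size_class_diameter(spec$size_class)
  base <- spec$base_render
  peak_test <- conserving_peak(base$peak_intensity, f_ref, f_test)

  draws <- with_seed(spec$seed, {
    list(seeds = sample.int(.Machine$integer.max - 1L, 2L * n),
         diam = pmax(rnorm(2L * n, mean_d, 0.08 * mean_d),
                     8 * base$pixel_size_um),
         ecc = runif(2L * n, 0, 0.3),
         ori = runif(2L * n, 0, pi))
  })

  groups <- rep(c("reference", "test"), each = n)
  ids <- sprintf("%s_%03d", ifelse(groups == "reference", "ref", "test"),
                 c(seq_len(n), seq_len(n)))
  images <- vector("list", 2L * n)
  regions <- vector("list", 2L * n)
  rows <- vector("list", 2L * n)
  for (i in seq_len(2L * n)) {
    is_test <- groups[i] == "test"
    rs <- nucleus_render_spec(
      diameter_um = draws$diam[i], pixel_size_um = base$pixel_size_um,
      eccentricity = draws$ecc[i], orientation = draws$ori[i],
      peak_intensity = if (is_test) peak_test else base$peak_intensity,
      noise = base$noise, gaussian_sd = base$gaussian_sd,
      seed = draws$seeds[i])
    rendered <- render_nucleus(if (is_test) f_test else f_ref, rs)
    images[[i]] <- rendered$image
    regions[[i]] <- rendered$region
    rows[[i]] <- data.frame(
      image_id = ids[i], group = groups[i], file = paste0(ids[i], ".tif"),
      seed = draws$seeds[i], diameter_um = draws$diam[i],
      eccentricity = draws$ecc[i], orientation = draws$ori[i],
      pixel_size_um = base$pixel_size_um,
      peak_intensity = if (is_test) peak_test else base$peak_intensity,
      center_row = rendered$region$center[1],
      center_col = rendered$region$center[2],
      radius_px = rendered$region$radius_px,
      stringsAsFactors = FALSE)
  }
  names(images) <- ids
  names(regions) <- ids
  manifest <- do.call(rbind, rows)
  cohort <- structure(list(images = images, regions = regions,
                           manifest = manifest, spec = spec),
                      class = "cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @rdname simulate_cohort
#' @param cohort a `cohort` object.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", dir),
                  call. = FALSE)
  }
  for (i in seq_along(cohort$images)) {
    write_image(cohort$images[[i]],
                file.path(dir, cohort$manifest$file[i]))
  }
  write_csv_table(cohort$manifest, file.path(dir, "manifest.csv"))
  sp <- cohort$spec
  write_config(list(
    n_per_group = sp$n_per_group, shift_fraction = sp$shift_fraction,
    size_class = sp$size_class, seed = sp$seed,
    law = unclass(sp$law),
    base_render = unclass(sp$base_render)
  ), file.path(dir, "cohort-spec.json"))
  invisible(dir)
}

manifest_schema <- c("image_id", "group", "file", "seed", "diameter_um",
                     "eccentricity", "orientation", "pixel_size_um",
                     "peak_intensity", "center_row", "center_col", "radius_px")

#' @rdname simulate_cohort
#' @export
read_manifest <- function(path) {
  read_csv_table(path, required = manifest_schema)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d nuclei per group, shift_fraction = %g, %s, seed = %d\n",
              x$spec$n_per_group, x$spec$shift_fraction, x$spec$size_class,
              x$spec$seed))
  invisible(x)
}
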