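#' Run configuration
#'
#' Collects the knobs of an end-to-end run. Any subset may be given; defaults
#' are filled in.
#'
#' @param image_dir directory of input TIFFs (for `run_measure`).
#' @param mask_dir optional directory of label-mask TIFFs named like the
#'   images; masks bypass segmentation entirely.
#' @param out_dir output directory.
#' @param seg segmentation parameters ([seg_params]).
#' @param ring_statistic `"sum"` or `"mean"` ([normalize_profile]).
#' @param bin_width interval width in percent; must divide 100.
#' @param alpha significance level in (0, 1).
#' @param correction `"none"`, `"holm"`, or `"BH"`.
#' @param intervals named list of interval sets for the change statistic.
#' @param seed master seed for simulation runs.
#' @return named list of class `run_config`.
#' @export
run_config <- function(image_dir = NULL, mask_dir = NULL, out_dir = ".",
                       seg = seg_params(), ring_statistic = "sum",
                       bin_width = 5, alpha = 0.05, correction = "none",
                       intervals = default_delta_intervals(), seed = 1L) {
  if (100 %% bin_width != 0) stop_field("bin_width", "must divide 100")
  if (alpha <= 0 || alpha >= 1) stop_field("alpha", "must lie in (0, 1)")
  structure(list(image_dir = image_dir, mask_dir = mask_dir,
                 out_dir = out_dir, seg = seg,
                 ring_statistic = ring_statistic, bin_width = bin_width,
                 alpha = alpha, correction = correction,
                 intervals = intervals, seed = as.integer(seed)),
            class = "run_config")
}

#' Simulate a cohort to disk
#'
#' Wraps [simulate_cohort]: renders the cohort, writes one TIFF per nucleus,
#' the manifest CSV, and the resolved cohort spec JSON into `out_dir`.
#'
#' @param spec a [cohort_spec].
#' @param out_dir output directory (created if missing).
#' @return the cohort, invisibly.
#' @export
run_simulate <- function(spec = cohort_spec(), out_dir) {
  cohort <- simulate_cohort(spec, dir = out_dir)
  message(sprintf("simulated %d nuclei into %s", nrow(cohort$manifest), out_dir))
  invisible(cohort)
}

#' Measure a directory of images into a profile table
#'
#' For every manifest row: read the image, pick the equatorial plane (for
#' stacks), segment (or load the provided mask), and profile every nucleus
#' into binned rows. Unreadable images are skipped with a warning, not fatal.
#'
#' @param manifest data.frame with columns `image_id`, `group`, `file`, or a
#'   path to such a CSV.
#' @param config a [run_config]; `image_dir` must point at the images.
#' @return [profile_table] with one row per nucleus and interval; written to
#'   `out_dir/profiles.csv` when `config$out_dir` is set.
#' @export
run_measure <- function(manifest, config = run_config()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  check_schema(manifest, c("image_id", "group", "file"), "manifest")
  tables <- list()
  skipped <- 0L
  for (i in seq_len(nrow(manifest))) {
    path <- file.path(config$image_dir, manifest$file[i])
    res <- tryCatch({
      img <- read_image(path)
      plane_idx <- 1L
      if (inherits(img, "image_stack")) {
        plane_idx <- select_equatorial_plane(img, config$seg)
        img <- img$planes[[plane_idx]]
      }
      mask <- NULL
      if (!is.null(config$mask_dir)) {
        mpath <- file.path(config$mask_dir, manifest$file[i])
        if (file.exists(mpath)) mask <- read_label_mask(mpath)
      }
      if (is.null(mask)) mask <- segment_nuclei(img, config$seg)
      regions <- nucleus_regions(mask, exclude_border = config$seg$exclude_border,
                                 plane_index = plane_idx)
      if (length(regions) == 0L) {
        warning(sprintf("no nuclei found in %s", path), call. = FALSE)
        NULL
      } else {
        for (reg in regions) {
          message(sprintf("%s: nucleus %d center (%.1f, %.1f) radius %.1f px plane %d",
                          manifest$image_id[i], reg$label, reg$center[1],
                          reg$center[2], reg$radius_px, reg$plane_index))
        }
        measure_plane(img, regions, image_id = manifest$image_id[i],
                      group = manifest$group[i],
                      ring_statistic = config$ring_statistic,
                      bin_width = config$bin_width, border = "clip")
      }
    }, error = function(e) {
      warning(sprintf("skipping %s: %s", path, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) skipped <- skipped + 1L else tables[[length(tables) + 1L]] <- res
  }
  if (length(tables) == 0L) stop("no image could be measured", call. = FALSE)
  out <- profile_table(do.call(rbind, tables))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_profile_table(out, file.path(config$out_dir, "profiles.csv"))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Compare two measured groups and write all outputs
#'
#' Reads two profile tables (CSV paths or data.frames), runs
#' [compare_cohorts], and writes the per-interval comparison CSV, the
#' interval-change JSON, and the comparison figure into `config$out_dir`.
#'
#' @param ref,test profile tables or CSV paths.
#' @param config a [run_config].
#' @return the `cohort_comparison`, invisibly.
#' @export
run_compare <- function(ref, test, config = run_config()) {
  if (is.character(ref)) ref <- read_profile_table(ref)
  if (is.character(test)) test <- read_profile_table(test)
  cmp <- compare_cohorts(ref, test, alpha = config$alpha,
                         correction = config$correction,
                         intervals = config$intervals)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    bins <- cmp$bins
    names(bins)[names(bins) == "p.value"] <- "p_value"
    names(bins)[names(bins) == "p.adjusted"] <- "p_adjusted"
    sum_cols <- function(s, who) {
      out <- s[, c("x", "n", "mean", "sd", "se")]
      names(out) <- c("x", paste(c("n", "mean", "sd", "se"), who, sep = "_"))
      out
    }
    full <- merge(sum_cols(cmp$summary_ref, "ref"),
                  sum_cols(cmp$summary_test, "test"), by = "x")
    full <- merge(full, bins[, c("x", "U", "p_value", "p_adjusted", "tested",
                                 "significant", "direction")], by = "x")
    write_csv_table(full, file.path(config$out_dir, "comparison.csv"))
    jsonlite::write_json(
      lapply(seq_len(nrow(cmp$deltas)), function(i) {
        list(interval = cmp$deltas$interval[i],
             bins = as.numeric(strsplit(cmp$deltas$bins[i], ";")[[1]]),
             delta_percent = cmp$deltas$delta_percent[i])
      }),
      file.path(config$out_dir, "deltas.json"), auto_unbox = TRUE, digits = NA)
    fig <- file.path(config$out_dir, "comparison.png")
    grDevices::png(fig, width = 1200, height = 800, res = 150)
    print(plot_radial_comparison(cmp))
    grDevices::dev.off()
  }
  invisible(cmp)
}

#' Verify a frameshift variant against a CDS
#'
#' Wraps [frameshift_report] for file input and prints the human-readable
#' report; optionally writes it as JSON.
#'
#' @param cds FASTA path or nucleotide string.
#' @param variant a [cds_variant] (default: the published lamin allele,
#'   [lam_a25_variant]).
#' @param json_path optional path for a JSON copy of the report.
#' @return the [frameshift_report], invisibly.
#' @export
run_verify_mutation <- function(cds, variant = lam_a25_variant(),
                                json_path = NULL) {
  report <- frameshift_report(read_cds(cds), variant)
  print(report)
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(report)
}

#' Measure a simulated cohort in memory
#'
#' Fast path for simulation studies: profiles every rendered nucleus of a
#' [simulate_cohort] result without touching disk. With `use_truth = TRUE`
#' (default) the ground-truth centre/radius is profiled directly; with
#' `use_truth = FALSE` each image is segmented first, exercising the full
#' measurement chain.
#'
#' @param cohort a `cohort` from [simulate_cohort].
#' @param use_truth profile ground-truth regions instead of re-segmenting.
#' @param config a [run_config] (segmentation and binning knobs).
#' @return [profile_table] with one row per nucleus and interval.
#' @export
measure_cohort <- function(cohort, use_truth = TRUE, config = run_config()) {
  rows <- vector("list", length(cohort$images))
  for (i in seq_along(cohort$images)) {
    img <- cohort$images[[i]]
    if (use_truth) {
      regions <- list(cohort$regions[[i]])
    } else {
      mask <- segment_nuclei(img, config$seg)
      regions <- nucleus_regions(mask, exclude_border = config$seg$exclude_border)
      if (length(regions) == 0L) next
    }
    rows[[i]] <- measure_plane(img, regions,
                               image_id = cohort$manifest$image_id[i],
                               group = cohort$manifest$group[i],
                               ring_statistic = config$ring_statistic,
                               bin_width = config$bin_width, border = "clip")
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  profile_table(do.call(rbind, rows))
}

#' Simulate, measure and compare in one call
#'
#' Runs a complete in-memory two-group experiment: simulate a cohort, profile
#' every nucleus, and compare the groups. The workhorse of the package's
#' simulation studies.
#'
#' @param spec a [cohort_spec].
#' @param use_truth profile ground-truth regions (fast) or re-segment.
#' @param config a [run_config].
#' @return a `cohort_comparison`.
#' @export
simulate_and_compare <- function(spec = cohort_spec(), use_truth = TRUE,
                                 config = run_config()) {
  cohort <- simulate_cohort(spec)
  tbl <- measure_cohort(cohort, use_truth = use_truth, config = config)
  df <- as.data.frame(tbl)
  compare_cohorts(profile_table(df[df$group == "reference", , drop = FALSE]),
                  profile_table(df[df$group == "test", , drop = FALSE]),
                  alpha = config$alpha, correction = config$correction,
                  intervals = config$intervals)
}
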