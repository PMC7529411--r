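test_that("radial laws have the specified shapes and validate their fields", {
  # constant law
  f <- radial_law(radial_law_spec("uniform", base_level = 0))
  expect_equal(f(c(0, 0.3, 1)), c(1, 1, 1))

  # degenerate mixture collapses to the pure rim law
  spec_mix <- radial_law_spec("mixture", mix_weight = 0, rim_center = 0.8,
                              rim_width = 0.1, base_level = 0.05)
  spec_rim <- radial_law_spec("peripheral_rim", rim_center = 0.8,
                              rim_width = 0.1, base_level = 0.05)
  rho <- seq(0, 1, length.out = 101)
  expect_equal(radial_law(spec_mix)(rho), radial_law(spec_rim)(rho))

  # rim peak location recovered by dense grid search
  f_rim <- radial_law(radial_law_spec("peripheral_rim", rim_center = 0.85))
  grid <- seq(0, 1, length.out = 10001)
  expect_equal(grid[which.max(f_rim(grid))], 0.85, tolerance = 1e-3)

  # nonnegativity across kinds
  for (kind in c("uniform", "peripheral_rim", "central_blob", "mixture")) {
    fk <- radial_law(radial_law_spec(kind, mix_weight = 0.4))
    expect_true(all(fk(grid) >= 0))
  }

  # validation errors name the offending field
  expect_error(radial_law_spec(mix_weight = 1.2), "mix_weight")
  expect_error(radial_law_spec(rim_center = -0.1), "rim_center")
  expect_error(radial_law_spec(rim_width = 0), "rim_width")
  expect_error(radial_law_spec(base_level = -1), "base_level")
  expect_error(radial_law_spec("ring"), "arg")
})

test_that("rendering is exact without noise and unbiased under Poisson noise", {
  rs <- nucleus_render_spec(diameter_um = 8, pixel_size_um = 0.2,
                            noise = "none")
  # uniform law: every in-nucleus pixel identical
  r <- render_nucleus(radial_law_spec("uniform", base_level = 0), rs)
  vals <- r$image$pixels[r$region$pixels]
  expect_equal(length(unique(vals)), 1L)
  expect_equal(vals[1], rs$peak_intensity)
  # outside the nucleus: background zero
  expect_true(all(r$image$pixels[-r$region$pixels] == 0))

  # noise = none: seed has no effect on the image
  law <- radial_law_spec("peripheral_rim")
  r1 <- render_nucleus(law, nucleus_render_spec(diameter_um = 8, noise = "none",
                                                seed = 1))
  r2 <- render_nucleus(law, nucleus_render_spec(diameter_um = 8, noise = "none",
                                                seed = 999))
  expect_identical(r1$image$pixels, r2$image$pixels)

  # Poisson noise is unbiased: 200 replicate renders vs the noiseless image
  expected <- render_nucleus(law, nucleus_render_spec(diameter_um = 5,
                                                      noise = "none"))
  acc <- 0
  for (k in 1:200) {
    acc <- acc + render_nucleus(law, nucleus_render_spec(
      diameter_um = 5, noise = "poisson", seed = 5000 + k))$image$pixels
  }
  mu <- expected$image$pixels[expected$region$pixels]
  mbar <- (acc / 200)[expected$region$pixels]
  z <- (mbar - mu) / sqrt(mu / 200)
  expect_gte(mean(abs(z) <= 3), 0.99)
  expect_lt(max(abs(z)), 5)

  # explicit canvas too small for the nucleus
  expect_error(
    render_nucleus(law, nucleus_render_spec(diameter_um = 20, pixel_size_um = 0.2,
                                            canvas_px = 50)),
    "does not fit")
  expect_error(nucleus_render_spec(diameter_um = 0.5, pixel_size_um = 0.2),
               "at least 3 pixels")
})

test_that("cohort simulation is deterministic and shift-free at zero shift", {
  # shift_fraction 0 leaves the law untouched
  law <- radial_law_spec("peripheral_rim")
  expect_identical(shift_law(law, 0), law)

  # identical specs give byte-identical manifests and images
  spec <- cohort_spec(n_per_group = 3, seed = 42)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$images[[1]]$pixels, c2$images[[1]]$pixels)
  expect_identical(c1$images[[6]]$pixels, c2$images[[6]]$pixels)
  expect_equal(nrow(c1$manifest), 6L)
  expect_equal(table(c1$manifest$group)[["reference"]], 3L)

  # manifest round-trips through the IO module
  dir <- withr::local_tempdir()
  write_cohort(c1, dir)
  m <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(m$image_id, c1$manifest$image_id)
  expect_equal(m$radius_px, c1$manifest$radius_px, tolerance = 1e-12)
})

test_that("a shifted law raises central intensity and conserves total mass", {
  law <- radial_law_spec("peripheral_rim")
  shifted <- shift_law(law, 0.3)
  # noiseless render of both laws = analytic expectation on the pixel grid
  base <- nucleus_render_spec(diameter_um = 11.1, pixel_size_um = 0.2,
                              noise = "none")
  r_ref <- render_nucleus(law, base)
  peak2 <- radialchrom:::conserving_peak(base$peak_intensity, radial_law(law),
                                         radial_law(shifted))
  r_test <- render_nucleus(shifted, nucleus_render_spec(
    diameter_um = 11.1, pixel_size_um = 0.2, noise = "none",
    peak_intensity = peak2))

  # mass conservation: the shift relocates intensity, it does not add it
  tot_ref <- sum(r_ref$image$pixels)
  tot_test <- sum(r_test$image$pixels)
  expect_lt(abs(tot_test - tot_ref) / tot_ref, 0.01)

  # central bins gain relative intensity in expectation
  bin_means <- function(r) {
    raw <- compute_raw_profile(r$image, r$region)
    bin_profile(normalize_profile(raw, ring_statistic = "mean"))
  }
  b_ref <- bin_means(r_ref)
  b_test <- bin_means(r_test)
  central <- b_ref$x <= 35
  expect_true(all(b_test$value[central] > b_ref$value[central]))
})

test_that("the normalized profile is invariant to the physical sampling scale", {
  # same law, same physical diameter, rendered at two pixel sizes: the
  # binned normalized profile must agree up to discretization error
  law <- radial_law_spec("peripheral_rim")
  render_at <- function(px_um) {
    r <- render_nucleus(law, nucleus_render_spec(
      diameter_um = 12, pixel_size_um = px_um, noise = "none"))
    bin_profile(normalize_profile(compute_raw_profile(r$image, r$region)))
  }
  fine <- render_at(0.05)    # radius 120 px
  coarse <- render_at(0.2)   # radius 30 px
  ok <- !is.na(fine$value) & !is.na(coarse$value)
  rms <- sqrt(mean((fine$value[ok] - coarse$value[ok])^2))
  expect_lt(rms, 0.05)
})
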