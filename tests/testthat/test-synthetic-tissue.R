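test_that("empty scene renders pure background with all-zero masks", {
  p <- scene_params(2, seed = 1, n_tumor_nuclei = 0, n_other_nuclei = 0)
  p$vasc_density <- 0
  patch <- render_scene(p)
  expect_true(all(patch$nuclei_mask == 0))
  expect_true(all(patch$vasc_mask == 0))
  # no nuclei anywhere: hematoxylin stays at the low background level
  hema <- rgb_to_hed(patch$image)[, , 1]
  expect_lt(max(hema), 0.2)
})

test_that("rendering is bit-deterministic given (params, seed)", {
  p <- scene_params(3, seed = 77)
  a <- render_scene(p)
  b <- render_scene(p)
  expect_identical(a$image, b$image)
  expect_identical(a$nuclei_mask, b$nuclei_mask)
  expect_identical(a$vasc_mask, b$vasc_mask)
})

test_that("requested nuclei appear as distinct components with the right area", {
  p <- scene_params(2, seed = 11, n_tumor_nuclei = 5, n_other_nuclei = 0)
  p$tumor_radius_mean <- 8
  p$vasc_density <- 0
  patch <- render_scene(p)
  # independent flood-fill oracle for the component count
  expect_equal(oracle_count_components(patch$nuclei_mask == 2), 5)
  lab <- label_components(patch$nuclei_mask == 2)
  areas <- tabulate(lab[lab > 0])
  expect_length(areas, 5)
  expect_true(all(abs(areas - pi * 64) / (pi * 64) < 0.15))
})

test_that("impossible placements fail with an informative constraint message", {
  p <- scene_params(4, seed = 1, patch_size = 32, n_tumor_nuclei = 40)
  expect_error(render_scene(p), "could not place nucleus")
  expect_error(render_scene(scene_params(1, seed = 1, patch_size = 16)),
               "patch_size")
})

test_that("cohort bookkeeping matches the requested design exactly", {
  co <- make_cohort(3, grade_levels = c(1, 4), n_slides = 2, seed = 9)
  expect_length(co$patches, 6)
  expect_equal(nrow(co$metadata), 6)
  expect_equal(as.numeric(table(co$metadata$grade)), c(3, 3))
  expect_setequal(unique(co$metadata$slide_id), c("S01", "S02"))
  # round-robin slides
  expect_equal(co$metadata$slide_id, rep(c("S01", "S02"), 3))
})

test_that("cohort morphology recovers the monotone grade rules from masks", {
  co <- std_cohort()
  ph <- purrr::map_dfr(co$patches, function(p) {
    m <- nuclear_morphometrics(p$nuclei_mask)$summary
    tibble::tibble(grade = p$grade_label,
                   tumor = m$mean_tumor_nuclear_area,
                   other = m$mean_other_nuclear_area,
                   vasc = vasculature_fraction(p$vasc_mask))
  })
  agg <- dplyr::summarise(dplyr::group_by(ph, grade),
                          tumor = mean(tumor), other = mean(other, na.rm = TRUE),
                          vasc = mean(vasc))
  expect_true(all(diff(agg$tumor) > 0))
  expect_true(all(diff(agg$vasc) < 0))
  # non-tumor nuclei are invariant to grade
  tt <- t.test(ph$other[ph$grade == 1], ph$other[ph$grade == 4])
  expect_gt(tt$p.value, 0.01)
})

test_that("vasculature density lands near its target fraction", {
  for (g in c(1, 4)) {
    p <- scene_params(g, seed = 21)
    patch <- render_scene(p)
    got <- mean(patch$vasc_mask != 0)
    expect_lt(abs(got - p$vasc_density) / p$vasc_density, 0.2)
  }
})

test_that("nucleus pixels are hematoxylin-dominant after stain deconvolution", {
  patch <- render_scene(scene_params(2, seed = 5))
  hema <- rgb_to_hed(patch$image)[, , 1]
  bg_median <- median(hema[patch$nuclei_mask == 0])
  expect_true(all(hema[patch$nuclei_mask > 0] > bg_median))
})

test_that("analytic backend round-trips codes bit-exactly", {
  b <- std_backend()
  p <- scene_params(2.7, seed = 13)
  patch <- render_scene(p)
  redo <- b$decode(b$encode(p), p$seed)
  expect_identical(redo$image, patch$image)
  expect_identical(redo$nuclei_mask, patch$nuclei_mask)
})

test_that("stochastic state moves positions but not grade-linked statistics", {
  b <- std_backend()
  code <- b$encode(scene_params(3, seed = 1))
  pa <- b$decode(code, 101)
  pb <- b$decode(code, 202)
  expect_false(identical(pa$nuclei_mask, pb$nuclei_mask))
  ra <- sqrt(nuclear_morphometrics(pa$nuclei_mask)$summary$mean_tumor_nuclear_area / pi)
  rb <- sqrt(nuclear_morphometrics(pb$nuclei_mask)$summary$mean_tumor_nuclear_area / pi)
  expect_lt(abs(ra - rb) / ra, 0.1)
})

test_that("moving along the exposed grade direction grows tumor nuclei", {
  b <- std_backend()
  code <- b$encode(scene_params(1, seed = 8))
  radii <- vapply(c(0, 1, 2, 3), function(t) {
    patch <- b$decode(code + t * b$grade_direction, 8)
    sqrt(nuclear_morphometrics(patch$nuclei_mask)$summary$mean_tumor_nuclear_area / pi)
  }, numeric(1))
  expect_true(all(diff(radii) > 0))
})

test_that("decoding out-of-bounds codes clips with a warning", {
  b <- std_backend()
  code <- b$encode(scene_params(1, seed = 3))
  code["vasc_density"] <- -0.2
  expect_warning(b$decode(code, 3), "clipped")
})

test_that("patch PNG round trip preserves image and masks", {
  patch <- render_scene(scene_params(2, seed = 31))
  stem <- file.path(withr::local_tempdir(), "p1")
  write_patch(patch, stem)
  back <- read_patch(stem, slide_id = "S1", grade_label = 2L)
  expect_equal(back$nuclei_mask, patch$nuclei_mask)
  expect_equal(back$vasc_mask, patch$vasc_mask)
  expect_lt(max(abs(back$image - patch$image)), 1 / 255)
})
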