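test_that("a never-terminal predictor runs exactly the step cap", {
  b <- std_backend()
  m <- std_model()
  p <- scene_params(1, seed = 4)
  stub <- function(patch) 99L   # never equals the target grade
  tr <- suppressWarnings(
    traverse_grade(b, b$encode(p), p$seed, m, stub, target_grade = 4,
                   max_steps = 4, n_nodes = 3))
  expect_equal(tr$n_shift_steps, 4L)
  expect_equal(tr$halted_by, "step_cap")
})

test_that("a zero step leaves the code and all node images unchanged", {
  b <- std_backend()
  m <- std_model()
  p <- scene_params(2, seed = 6)
  tr <- traverse_grade(b, b$encode(p), p$seed, m, std_predictor(),
                       target_grade = 4, step_scale = 0, max_steps = 2,
                       n_nodes = 4)
  expect_equal(tr$end_code, tr$start_code)
  imgs <- purrr::map(tr$nodes$patch, "image")
  for (img in imgs[-1]) expect_identical(img, imgs[[1]])
})

test_that("node codes are collinear in standardized space", {
  tr <- std_trajectory()
  m <- tr$model
  z0 <- standardize(tr$start_code, m)
  z1 <- standardize(tr$end_code, m)
  for (i in seq_len(nrow(tr$nodes))) {
    want <- z0 + tr$nodes$frac[i] * (z1 - z0)
    expect_lt(max(abs(standardize(tr$nodes$code[[i]], m) - want)), 1e-8)
  }
})

test_that("trajectories keep one stochastic state and 20 interior nodes", {
  tr <- std_trajectory()
  expect_equal(sum(tr$nodes$role == "interior"), 20)
  seeds <- purrr::map_int(tr$nodes$patch, ~ .x$params$seed)
  expect_true(all(seeds == tr$state))
})

test_that("the target-class logit increases strictly along the walk", {
  tr <- std_trajectory()
  m <- tr$model
  codes <- do.call(rbind, tr$nodes$code)
  lg <- class_logits(m, codes)[, as.character(tr$direction_class)]
  expect_true(all(diff(lg) > 0))
})

test_that("grade-up trajectories grow tumor nuclei monotonically", {
  tr <- std_trajectory()
  areas <- purrr::map_dbl(tr$nodes$patch,
                          ~ nuclear_morphometrics(.x$nuclei_mask)$summary$mean_tumor_nuclear_area)
  # non-decreasing up to pixelation noise on adjacent nodes
  expect_true(all(diff(areas) > -3))
  expect_gt(areas[length(areas)] - areas[1], 50)
  expect_equal(tr$nodes$pred_grade[nrow(tr$nodes)], 4L)
})

test_that("grade-down from grade 4 shrinks tumor nuclei", {
  b <- std_backend()
  m <- std_model()
  p <- scene_params(4, seed = 40)
  tr <- grade_down(b, b$encode(p), p$seed, m, std_predictor(), n_nodes = 6)
  areas <- purrr::map_dbl(tr$nodes$patch,
                          ~ nuclear_morphometrics(.x$nuclei_mask)$summary$mean_tumor_nuclear_area)
  expect_true(all(diff(areas) < 3))
  expect_lt(areas[length(areas)], areas[1])
  expect_equal(tr$direction_class, 1)
})

test_that("a start already at the target yields a degenerate zero-shift trajectory", {
  b <- std_backend()
  m <- std_model()
  p <- scene_params(4, seed = 50)
  tr <- traverse_grade(b, b$encode(p), p$seed, m, std_predictor(),
                       target_grade = std_predictor()(render_scene(p)),
                       n_nodes = 3)
  expect_equal(tr$n_shift_steps, 0L)
  expect_equal(tr$end_code, tr$start_code)
})

test_that("most grade-1 starts reach grade 4 within the step cap", {
  b <- std_backend()
  m <- std_model()
  co <- std_cohort()
  idx <- which(co$metadata$grade == 1)[1:25]
  done <- vapply(idx, function(i) {
    p <- co$patches[[i]]
    tr <- traverse_grade(b, b$encode(p$params), p$params$seed, m,
                         std_predictor(), target_grade = 4, n_nodes = 2)
    tr$halted_by == "terminal_grade" &&
      tr$nodes$pred_grade[nrow(tr$nodes)] == 4L
  }, logical(1))
  expect_gte(mean(done), 0.8)
})

test_that("within-grade swaps keep state A and statistics B", {
  b <- std_backend()
  pa <- render_scene(scene_params(2, seed = 61, slide_id = "S01"))
  pb <- render_scene(scene_params(2, seed = 62, slide_id = "S02"))
  pb$params$tumor_radius_mean <- 6.5   # B differs in grade-linked statistics
  pb <- render_scene(pb$params)
  # self-swap reconstructs the original bit-exactly
  self <- within_grade_swap(pa, pa, b)
  expect_identical(self$image, pa$image)
  out <- within_grade_swap(pa, pb, b)
  expect_identical(dim(out$image), dim(pa$image))
  # decoded with A's seed and B's code: bit-equal to rendering B's params at A's seed
  ref_params <- pb$params
  ref_params$seed <- pa$params$seed
  expect_identical(out$nuclei_mask, render_scene(ref_params)$nuclei_mask)
  r_out <- sqrt(nuclear_morphometrics(out$nuclei_mask)$summary$mean_tumor_nuclear_area / pi)
  expect_lt(abs(r_out - 6.5) / 6.5, 0.12)
  # same slide is rejected; different grades are rejected
  pb$slide_id <- "S01"
  expect_error(within_grade_swap(pa, pb, b), "different slides")
  pc <- render_scene(scene_params(4, seed = 63, slide_id = "S03"))
  expect_error(within_grade_swap(pa, pc, b), "grade label")
})
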